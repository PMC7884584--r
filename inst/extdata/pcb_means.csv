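species,analyte_id,mean
nile_tilapia,PCB28,0.02
nile_tilapia,PCB52,0.10
nile_tilapia,PCB101,<LOD
nile_tilapia,PCB138,0.01
nile_tilapia,PCB153,<LOD
nile_tilapia,PCB180,<LOD
nile_tilapia,PCB105,0.01
nile_tilapia,PCB114,<LOD
nile_tilapia,PCB118,<LOD
nile_tilapia,PCB123,<LOD
nile_tilapia,PCB156,<LOD
nile_tilapia,PCB157,0.01
nile_tilapia,PCB167,<LOD
nile_tilapia,PCB189,<LOD
nile_tilapia,PCB77,0.01
nile_tilapia,PCB81,0.07
nile_tilapia,PCB126,0.02
nile_tilapia,PCB169,0.05
panga,PCB28,0.01
panga,PCB52,0.06
panga,PCB101,<LOD
panga,PCB138,<LOD
panga,PCB153,<LOD
panga,PCB180,<LOD
panga,PCB105,0.01
panga,PCB114,<LOD
panga,PCB118,<LOD
panga,PCB123,<LOD
panga,PCB156,<LOD
panga,PCB157,<LOD
panga,PCB167,<LOD
panga,PCB189,0.02
panga,PCB77,0.01
panga,PCB81,0.04
panga,PCB126,0.02
panga,PCB169,0.04
pacific_cod,PCB28,0.03
pacific_cod,PCB52,0.06
pacific_cod,PCB101,0.02
pacific_cod,PCB138,0.03
pacific_cod,PCB153,0.03
pacific_cod,PCB180,<LOD
pacific_cod,PCB105,0.02
pacific_cod,PCB114,<LOD
pacific_cod,PCB118,0.02
pacific_cod,PCB123,0.03
pacific_cod,PCB156,<LOD
pacific_cod,PCB157,0.01
pacific_cod,PCB167,<LOD
pacific_cod,PCB189,<LOD
pacific_cod,PCB77,0.01
pacific_cod,PCB81,0.05
pacific_cod,PCB126,0.04
pacific_cod,PCB169,0.06
pollock,PCB28,0.02
pollock,PCB52,0.05
pollock,PCB101,0.01
pollock,PCB138,0.01
pollock,PCB153,0.01
pollock,PCB180,<LOD
pollock,PCB105,0.01
pollock,PCB114,<LOD
pollock,PCB118,0.01
pollock,PCB123,<LOD
pollock,PCB156,<LOD
pollock,PCB157,<LOD
pollock,PCB167,<LOD
pollock,PCB189,<LOD
pollock,PCB77,<LOD
pollock,PCB81,0.05
pollock,PCB126,0.02
pollock,PCB169,0.05
yellowfin_sole,PCB28,0.02
yellowfin_sole,PCB52,0.05
yellowfin_sole,PCB101,0.01
yellowfin_sole,PCB138,0.03
yellowfin_sole,PCB153,0.05
yellowfin_sole,PCB180,0.01
yellowfin_sole,PCB105,<LOD
yellowfin_sole,PCB114,<LOD
yellowfin_sole,PCB118,0.02
yellowfin_sole,PCB123,0.03
yellowfin_sole,PCB156,<LOD
yellowfin_sole,PCB157,<LOD
yellowfin_sole,PCB167,0.01
yellowfin_sole,PCB189,<LOD
yellowfin_sole,PCB77,<LOD
yellowfin_sole,PCB81,0.03
yellowfin_sole,PCB126,0.03
yellowfin_sole,PCB169,0.04
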