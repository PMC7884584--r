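# Reference constants for the fish-product risk screening pipeline.
# All concentrations are ng/g wet weight unless stated otherwise.
#
# tef: WHO 2005 toxic equivalency factors for the 12 dioxin-like PCB
#      congeners (non-ortho 77/81/126/169; mono-ortho 105/114/118/123/
#      156/157/167/189), as consolidated in Commission Regulation (EU)
#      No 1259/2011.
# rfd: chronic oral reference doses, mg/kg/day. US EPA IRIS values where
#      a listing exists; isomers and metabolites without their own
#      listing use the parent compound as surrogate (HCH isomers ->
#      lindane; DDD/DDE -> DDT; endosulfan alpha/beta/sulfate ->
#      endosulfan; endrin ketone -> endrin).
# lod/loq: detection and quantification limits, ng/g. Pesticide LOD is
#      0.01 on average; pesticide LOQs as reported per compound; PCB LOQ
#      defaults to the midpoint of the reported 0.03-0.1 range.
# intake: adc_hq is the daily fish consumption used on the pesticide HQ
#      path (g/day); adc_teq the one used on the TEQ/weekly-intake path
#      (12.48 kg/yr -> 34.19 g/day); bw the adult body weight (kg).
# twi: tolerable weekly intakes, pg-TEQ/kg bw/week (former 14, current 2).
tef:
  PCB77: 0.0001
  PCB81: 0.0003
  PCB126: 0.1
  PCB169: 0.03
  PCB105: 0.00003
  PCB114: 0.00003
  PCB118: 0.00003
  PCB123: 0.00003
  PCB156: 0.00003
  PCB157: 0.00003
  PCB167: 0.00003
  PCB189: 0.00003
rfd:
  aHCH: 0.0003
  bHCH: 0.0003
  gHCH: 0.0003
  dHCH: 0.0003
  aldrin: 0.00003
  dieldrin: 0.00005
  pp_DDT: 0.0005
  pp_DDD: 0.0005
  pp_DDE: 0.0005
  endosulfan_a: 0.006
  endosulfan_b: 0.006
  endosulfan_sulfate: 0.006
  heptachlor: 0.0005
  endrin_ketone: 0.0003
  methoxychlor: 0.005
lod:
  default_ocp: 0.01
  default_pcb: 0.01
loq:
  aHCH: 0.01
  bHCH: 0.01
  gHCH: 0.01
  pp_DDT: 0.01
  pp_DDD: 0.05
  pp_DDE: 0.06
  dieldrin: 0.06
  heptachlor: 0.4
  default_ocp: 0.01
  default_pcb: 0.065
intake:
  adc_hq: 34.30
  adc_teq: 34.19
  bw: 70
twi:
  old: 14
  new: 2
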