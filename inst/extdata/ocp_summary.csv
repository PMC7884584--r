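species,analyte_id,mean,sd,min,max,median,cv
nile_tilapia,aHCH,0.5069,0.1562,0.2654,0.8108,0.5373,30.82
nile_tilapia,bHCH,0.2222,0.1533,0.0765,0.6594,0.1681,68.98
nile_tilapia,gHCH,0.1177,0.0621,0.0497,0.2539,0.0914,52.73
nile_tilapia,dHCH,0.6168,0.1740,0.4422,1.1263,0.5904,28.21
nile_tilapia,aldrin,0.0201,0.0058,0.0114,0.0307,0.0206,29.26
nile_tilapia,dieldrin,0.1356,0.0252,0.0868,0.1735,0.1396,18.64
nile_tilapia,pp_DDT,0.0470,0.0568,<LOD,0.1292,<LOD,120.74
nile_tilapia,pp_DDD,0.1321,0.0184,0.1062,0.1597,0.1301,14.00
nile_tilapia,pp_DDE,0.0284,0.0047,0.0229,0.0368,0.0281,16.63
nile_tilapia,endosulfan_a,0.0285,0.0035,0.0233,0.0347,0.0276,12.56
nile_tilapia,endosulfan_b,0.0293,0.0277,<LOD,0.0700,0.0396,94.59
nile_tilapia,endosulfan_sulfate,0.1073,0.0547,0.0608,0.2329,0.0810,50.99
nile_tilapia,heptachlor,0.1374,0.0356,0.0944,0.2339,0.1309,25.96
nile_tilapia,endrin_ketone,0.1077,0.0274,0.0738,0.1858,0.1032,25.48
nile_tilapia,methoxychlor,0.1055,0.0135,0.0908,0.1350,0.1014,12.81
panga,aHCH,0.4529,0.1635,0.1126,0.7243,0.4593,36.09
panga,bHCH,0.0907,0.0729,0.0323,0.2829,0.0550,80.29
panga,gHCH,0.0559,0.0459,0.0224,0.1589,0.0324,82.06
panga,dHCH,0.6663,0.5364,0.1790,2.1662,0.5050,80.50
panga,aldrin,0.0386,0.0938,0.0058,0.3898,0.0150,243.11
panga,dieldrin,0.0580,0.0195,0.0190,0.0851,0.0607,33.65
panga,pp_DDT,0.0502,0.0924,<LOD,0.3243,<LOD,184.08
panga,pp_DDD,0.0661,0.0101,0.0523,0.0957,0.0637,15.38
panga,pp_DDE,0.0187,0.0034,0.0147,0.0284,0.0182,18.34
panga,endosulfan_a,0.0218,0.0062,0.0145,0.0409,0.0206,28.79
panga,endosulfan_b,0.0256,0.0162,<LOD,0.0471,0.0319,63.43
panga,endosulfan_sulfate,0.0535,0.0232,<LOD,0.0864,0.0586,43.38
panga,heptachlor,0.1152,0.0438,0.0539,0.2070,0.1078,38.02
panga,endrin_ketone,0.0489,0.0214,<LOD,0.0823,0.0524,43.88
panga,methoxychlor,0.0890,0.0277,0.0590,0.1382,0.0765,31.19
pacific_cod,aHCH,0.2870,0.0365,0.2513,0.3382,0.2793,12.74
pacific_cod,bHCH,0.0385,0.0026,0.0359,0.0410,0.0385,6.79
pacific_cod,gHCH,0.0292,0.0020,0.0269,0.0317,0.0291,6.88
pacific_cod,dHCH,0.2324,0.0632,0.1730,0.3165,0.2200,27.21
pacific_cod,aldrin,0.0188,0.0030,0.0154,0.0218,0.0191,15.99
pacific_cod,dieldrin,0.2986,0.0606,0.2173,0.3483,0.3145,20.29
pacific_cod,pp_DDT,<LOD,<LOD,<LOD,<LOD,<LOD,
pacific_cod,pp_DDD,0.1384,0.0238,0.1173,0.1706,0.1327,17.26
pacific_cod,pp_DDE,0.0278,0.0016,0.0259,0.0298,0.0278,5.96
pacific_cod,endosulfan_a,0.0251,0.0009,0.0242,0.0262,0.0250,3.84
pacific_cod,endosulfan_b,<LOD,<LOD,<LOD,<LOD,<LOD,
pacific_cod,endosulfan_sulfate,0.0677,0.0076,0.0588,0.0743,0.0689,11.24
pacific_cod,heptachlor,0.1508,0.0188,0.1294,0.1745,0.1496,12.53
pacific_cod,endrin_ketone,0.0699,0.0060,0.0612,0.0743,0.0722,8.69
pacific_cod,methoxychlor,0.0885,0.0018,0.0870,0.0909,0.0881,2.13
pollock,aHCH,0.2766,0.0232,0.2536,0.3055,0.2736,8.42
pollock,bHCH,0.0366,0.0045,0.0308,0.0414,0.0372,12.33
pollock,gHCH,0.0259,0.0030,0.0217,0.0290,0.0264,11.80
pollock,dHCH,<LOD,<LOD,<LOD,<LOD,<LOD,
pollock,aldrin,0.0199,0.0012,0.0185,0.0216,0.0198,6.27
pollock,dieldrin,0.1336,0.0069,0.1283,0.1430,0.1315,5.18
pollock,pp_DDT,<LOD,<LOD,<LOD,<LOD,<LOD,
pollock,pp_DDD,0.0930,0.0053,0.0876,0.0987,0.0929,5.78
pollock,pp_DDE,0.0220,0.0032,0.0185,0.0253,0.0221,14.78
pollock,endosulfan_a,0.0232,0.0020,0.0206,0.0250,0.0235,8.60
pollock,endosulfan_b,0.0385,0.0027,0.0357,0.0411,0.0387,6.99
pollock,endosulfan_sulfate,0.0770,0.0077,0.0697,0.0881,0.0752,10.11
pollock,heptachlor,0.1150,0.0221,0.0968,0.1453,0.1090,19.26
pollock,endrin_ketone,0.0678,0.0049,0.0629,0.0739,0.0671,7.25
pollock,methoxychlor,0.0907,0.0081,0.0823,0.1018,0.0893,8.93
yellowfin_sole,aHCH,0.2868,0.0363,0.2379,0.3227,0.2933,12.66
yellowfin_sole,bHCH,0.0360,0.0075,0.0294,0.0463,0.0341,21.04
yellowfin_sole,gHCH,0.0291,0.0051,0.0219,0.0333,0.0306,17.51
yellowfin_sole,dHCH,0.2053,0.0181,0.1812,0.2251,0.2074,8.85
yellowfin_sole,aldrin,0.0114,0.0014,0.0094,0.0126,0.0118,12.59
yellowfin_sole,dieldrin,0.1145,0.0262,0.0849,0.1394,0.1168,22.92
yellowfin_sole,pp_DDT,<LOD,<LOD,<LOD,<LOD,<LOD,
yellowfin_sole,pp_DDD,0.0948,0.0151,0.0723,0.1046,0.1011,16.02
yellowfin_sole,pp_DDE,0.0213,0.0014,0.0198,0.0228,0.0213,6.83
yellowfin_sole,endosulfan_a,0.0205,0.0006,0.0198,0.0212,0.0205,3.38
yellowfin_sole,endosulfan_b,<LOD,<LOD,<LOD,<LOD,<LOD,
yellowfin_sole,endosulfan_sulfate,0.0740,0.0234,0.0489,0.1018,0.0727,31.59
yellowfin_sole,heptachlor,0.0817,0.0164,0.0670,0.0984,0.0808,20.05
yellowfin_sole,endrin_ketone,0.0645,0.0067,0.0546,0.0699,0.0667,10.52
yellowfin_sole,methoxychlor,0.0792,0.0074,0.0689,0.0867,0.0805,9.40
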