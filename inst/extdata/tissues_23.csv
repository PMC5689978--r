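low,high,name,H,C,N,O,Na,Mg,P,S,Cl,Ar,K,Ca
0.0012,0.05,air,0,0,0.755,0.232,0,0,0,0,0,0.013,0,0
0.05,0.3,lung_inflated,0.103,0.105,0.031,0.749,0.002,0,0.002,0.003,0.003,0,0.002,0
0.3,0.5,lung_partial,0.103,0.105,0.031,0.749,0.002,0,0.002,0.003,0.003,0,0.002,0
0.5,0.7,adipose_lung,0.108,0.347,0.021,0.516,0.001,0,0.001,0.002,0.002,0,0.002,0
0.7,0.85,adipose_low,0.112,0.508,0.013,0.364,0.001,0,0,0.001,0.001,0,0,0
0.85,0.9,adipose_3,0.116,0.681,0.002,0.198,0.001,0,0,0.001,0.001,0,0,0
0.9,0.93,adipose_2,0.114,0.598,0.007,0.278,0.001,0,0,0.001,0.001,0,0,0
0.93,0.96,adipose_1,0.112,0.517,0.013,0.355,0.001,0,0,0.001,0.001,0,0,0
0.96,0.99,mammary,0.109,0.506,0.023,0.358,0.001,0,0.001,0.001,0.001,0,0,0
0.99,1.01,soft_water,0.112,0,0,0.888,0,0,0,0,0,0,0,0
1.01,1.03,muscle,0.102,0.143,0.034,0.71,0.001,0,0.002,0.003,0.001,0,0.004,0
1.03,1.06,liver,0.102,0.139,0.03,0.716,0.002,0,0.003,0.003,0.002,0,0.003,0
1.06,1.1,connective,0.094,0.207,0.062,0.622,0.006,0,0,0.006,0.003,0,0,0
1.1,1.15,cartilage,0.096,0.099,0.022,0.744,0.005,0,0.022,0.009,0.003,0,0,0
1.15,1.25,bone_01,0.085,0.404,0.028,0.367,0.001,0.001,0.034,0.002,0.002,0,0.001,0.075
1.25,1.35,bone_02,0.078625,0.372875,0.02975,0.3750625,0.001,0.001125,0.042875,0.002125,0.0018125,0,0.001,0.09375
1.35,1.45,bone_03,0.07225,0.34175,0.0315,0.383125,0.001,0.00125,0.05175,0.00225,0.001625,0,0.001,0.1125
1.45,1.55,bone_04,0.065875,0.310625,0.03325,0.3911875,0.001,0.001375,0.060625,0.002375,0.0014375,0,0.001,0.13125
1.55,1.7,bone_05,0.0595,0.2795,0.035,0.39925,0.001,0.0015,0.0695,0.0025,0.00125,0,0.001,0.15
1.7,1.85,bone_06,0.053125,0.248375,0.03675,0.4073125,0.001,0.001625,0.078375,0.002625,0.0010625,0,0.001,0.16875
1.85,2,bone_07,0.04675,0.21725,0.0385,0.415375,0.001,0.00175,0.08725,0.00275,0.000875,0,0.001,0.1875
2,2.3,bone_08,0.040375,0.186125,0.04025,0.4234375,0.001,0.001875,0.096125,0.002875,0.0006875,0,0.001,0.20625
2.3,3,bone_09,0.034,0.155,0.042,0.4315,0.001,0.002,0.105,0.003,5e-04,0,0.001,0.225
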