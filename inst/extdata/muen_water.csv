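energy_mev,muen_over_rho
0.01,4.944
0.015,1.374
0.02,0.5503
0.03,0.1557
0.04,0.06947
0.05,0.04223
0.06,0.0319
0.08,0.02597
0.1,0.02546
0.15,0.02764
0.2,0.02967
0.3,0.03192
0.4,0.03279
0.5,0.03299
0.6,0.03284
0.8,0.03206
1,0.03103
1.25,0.02965
1.5,0.02833
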