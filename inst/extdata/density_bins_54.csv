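low,high,representative
0.0012,0.05,0.0012
0.05,0.1,0.075
0.1,0.15,0.12
0.15,0.2,0.18
0.2,0.25,0.22
0.25,0.3,0.27
0.3,0.35,0.32
0.35,0.4,0.37
0.4,0.45,0.43
0.45,0.5,0.47
0.5,0.55,0.52
0.55,0.6,0.58
0.6,0.65,0.63
0.65,0.7,0.67
0.7,0.75,0.73
0.75,0.8,0.78
0.8,0.85,0.82
0.85,0.87,0.86
0.87,0.89,0.88
0.89,0.91,0.9
0.91,0.93,0.92
0.93,0.95,0.94
0.95,0.97,0.96
0.97,0.99,0.98
0.99,1.01,1
1.01,1.03,1.02
1.03,1.05,1.04
1.05,1.07,1.06
1.07,1.09,1.08
1.09,1.11,1.1
1.11,1.13,1.12
1.13,1.15,1.14
1.15,1.2,1.175
1.2,1.25,1.2
1.25,1.3,1.275
1.3,1.35,1.3
1.35,1.4,1.375
1.4,1.45,1.4
1.45,1.5,1.475
1.5,1.55,1.5
1.55,1.6,1.575
1.6,1.65,1.6
1.65,1.7,1.675
1.7,1.75,1.7
1.75,1.8,1.775
1.8,1.85,1.8
1.85,1.9,1.875
1.9,1.95,1.9
1.95,2,1.975
2,2.05,2
2.05,2.1,2.075
2.1,2.15,2.1
2.15,2.2,2.175
2.2,3,2.6
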