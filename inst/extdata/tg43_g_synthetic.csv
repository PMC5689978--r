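r_cm,g
0.25,0.98303125
0.4,0.98674
0.5,0.989125
0.6,0.99144
0.8,0.99586
1,1
1.25,1.00478125
1.5,1.009125
1.75,1.01303125
2,1.0165
2.5,1.022125
3,1.026
3.5,1.028125
4,1.0285
4.5,1.027125
5,1.024
6,1.0125
7,0.994
8,0.9685
10,0.8965
12,0.7965
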