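energy_mev,intensity
0.20579,0.0334
0.29596,0.2871
0.30846,0.297
0.31651,0.8286
0.46807,0.4784
0.48458,0.03189
0.58858,0.04522
0.60441,0.08216
0.61246,0.0534
0.88454,0.00293
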