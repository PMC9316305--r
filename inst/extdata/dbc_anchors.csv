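residence_time_min,dbc10_g_per_l
0.1,35.2
0.2,40.1
0.3333333333333333,43.1
2.0,50.1
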