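state,00,01,10,11
00,0.9801,0.0099,0.0099,1e-04
01,0.0361,0.1539,0.1539,0.6561
10,0.0361,0.1539,0.1539,0.6561
11,0.1881,0.0019,0.8019,0.0081
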