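state,0000,0001,0010,0011,0100,0101,0110,0111,1000,1001,1010,1011,1100,1101,1110,1111
0000,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
0001,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
0010,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
0011,1e-04,9e-04,9e-04,0.0081,9e-04,0.0081,0.0081,0.0729,9e-04,0.0081,0.0081,0.0729,0.0081,0.0729,0.0729,0.6561
0100,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
0101,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
0110,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
0111,1e-04,9e-04,9e-04,0.0081,9e-04,0.0081,0.0081,0.0729,9e-04,0.0081,0.0081,0.0729,0.0081,0.0729,0.0729,0.6561
1000,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
1001,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
1010,0.6561,0.0729,0.0729,0.0081,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.0081,9e-04,9e-04,1e-04
1011,1e-04,9e-04,9e-04,0.0081,9e-04,0.0081,0.0081,0.0729,9e-04,0.0081,0.0081,0.0729,0.0081,0.0729,0.0729,0.6561
1100,1e-04,9e-04,9e-04,0.0081,9e-04,0.0081,0.0081,0.0729,9e-04,0.0081,0.0081,0.0729,0.0081,0.0729,0.0729,0.6561
1101,1e-04,9e-04,9e-04,0.0081,9e-04,0.0081,0.0081,0.0729,9e-04,0.0081,0.0081,0.0729,0.0081,0.0729,0.0729,0.6561
1110,1e-04,9e-04,9e-04,0.0081,9e-04,0.0081,0.0081,0.0729,9e-04,0.0081,0.0081,0.0729,0.0081,0.0729,0.0729,0.6561
1111,0.0081,9e-04,9e-04,1e-04,0.0729,0.0081,0.0081,9e-04,0.0729,0.0081,0.0081,9e-04,0.6561,0.0729,0.0729,0.0081
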