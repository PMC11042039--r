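A,B,C,D,E,F
2,0,100,0.2,2,0
5,51,400,0.7,0,1
NA,23,100,0.9,3,0
7,0,200,0.8,5,1
1,11,0,0.1,4,0
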