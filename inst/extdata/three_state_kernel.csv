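0,1,2
0.9425,0.0475,0.0100
0.3500,0.3000,0.3500
0.0100,0.0475,0.9425
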