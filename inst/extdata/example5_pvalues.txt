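0.005
0.049
0.050
0.051
0.700
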