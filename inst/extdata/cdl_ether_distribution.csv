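ether_count,fraction
0,0.09
1,0.12
2,0.28
3,0.18
4,0.33
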