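stratum,dld,tld
4,46,14
3,57,38
2,28,71
1,27,104
0,27,268
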