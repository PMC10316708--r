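stratum,dld,tld
3-4,12,14
2,5,23
1,3,29
0,1,41
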