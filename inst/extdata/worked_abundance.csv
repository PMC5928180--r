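endmember,abundance
1,0.48
2,0.49
3,0.015
4,0.015
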