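reference_gg,1,2,3,4
1,19,4,0,1
2,1,2,1,0
3,2,0,2,1
4,0,1,3,3
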