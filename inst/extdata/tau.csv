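support,value
0,0.7
1,0.3
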