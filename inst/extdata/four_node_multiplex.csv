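source,target,layer
1,2,A
2,3,A
3,4,A
1,3,B
2,4,B
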