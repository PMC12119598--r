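group,x,y
1,43,44
1,33,50
1,19,37
1,7,38
1,53,61
2,52,45
2,11,27
2,22,26
2,40,45
2,35,32
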