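score,count
20,1
18,1
12,5
9,2
7,5
6,9
5,30
4,26
3,201
2,50
1,1454
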