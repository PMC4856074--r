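lg,VI,II,III,VII,VIII,I,IV,V,XIII,XI,IX,X,XII
1,8,0,0,0,0,0,0,0,0,0,0,0,0
2,0,10,0,0,0,0,0,0,0,0,0,0,0
3,0,0,8,0,0,0,0,0,0,1,0,0,0
4,0,0,0,8,0,0,0,0,0,0,0,0,0
5,0,0,0,0,8,0,0,0,0,1,0,0,0
6,0,0,0,0,0,11,0,0,0,0,0,0,0
7,0,0,0,0,0,0,10,0,0,0,0,0,0
8,0,0,0,0,0,0,0,6,0,0,0,0,0
9,0,0,0,0,0,0,0,0,3,0,0,0,0
10,0,0,0,0,0,0,0,0,0,3,0,0,0
11,0,0,0,0,0,0,0,0,0,0,7,0,0
12,0,0,0,0,0,0,0,0,0,0,0,3,0
13,0,0,0,0,0,0,0,0,0,0,0,0,4
14,0,0,1,0,0,0,0,0,0,0,0,0,0
15,0,0,0,0,0,0,0,0,0,0,2,0,0
16,0,0,0,0,2,0,0,0,0,0,0,0,0
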