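residue,category
3,cationic
5,cationic
8,cationic
11,cationic
14,cationic
17,cationic
20,cationic
22,cationic
25,catalytic
28,catalytic
30,catalytic
33,catalytic
35,catalytic
38,catalytic
40,catalytic
2,interface
3,interface
5,interface
8,interface
10,interface
11,interface
14,interface
17,interface
20,interface
22,interface
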