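time,X
0,20
2,18
4,18
6,18
8,19
10,19
12,20
14,20
16,23
18,22
20,22
22,21
24,17
26,19
28,20
30,19
32,17
34,19
36,19
38,21
40,21
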