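channel,region,side
8,PMA,left
9,PMA,left
10,PMA,left
11,PMA,right
12,PMA,right
13,PMA,right
17,SMA,left
18,SMA,right
16,hand_M1,left
21,hand_M1,left
22,hand_M1,left
26,hand_M1,left
19,hand_M1,right
23,hand_M1,right
24,hand_M1,right
27,hand_M1,right
1,mouth_M1,left
6,mouth_M1,left
20,mouth_M1,left
5,mouth_M1,right
15,mouth_M1,right
25,mouth_M1,right
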