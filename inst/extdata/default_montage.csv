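channel,source,detector,roi,hemisphere
1,1,1,FPA,left
2,1,2,FPA,left
3,2,3,FPA,left
4,2,4,DLPFC,left
5,3,5,DLPFC,left
6,3,6,DLPFC,left
7,4,7,DLPFC,left
8,4,8,VLPFC,left
9,5,9,VLPFC,left
10,5,10,VLPFC,left
11,6,11,PM&SMA,left
12,6,12,PM&SMA,left
13,7,13,PM&SMA,left
14,7,14,S1,left
15,8,15,S1,left
16,8,16,S1,left
17,9,1,V1,left
18,9,2,V1,left
19,10,3,V1,left
20,10,4,FPA,right
21,11,5,FPA,right
22,11,6,FPA,right
23,12,7,DLPFC,right
24,12,8,DLPFC,right
25,13,9,DLPFC,right
26,13,10,DLPFC,right
27,14,11,VLPFC,right
28,14,12,VLPFC,right
29,15,13,VLPFC,right
30,15,14,PM&SMA,right
31,16,15,PM&SMA,right
32,16,16,PM&SMA,right
33,17,1,S1,right
34,17,2,S1,right
35,18,3,S1,right
36,18,4,V1,right
37,19,5,V1,right
38,19,6,V1,right
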