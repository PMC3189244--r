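id,tissue,stain,core_diameter_um,total_cores,missing_cores,fragmented_cores,remaining_cores
1,Lung,BAK,600,232,6,0,226
2,Lung,BAX,600,232,5,0,227
3,Lung,H&E,600,232,3,0,229
4,Lung,CB1,600,232,7,2,223
5,Lung,Negative Control,600,232,8,0,224
6,Lung,NOXA,600,232,7,0,225
7,Lung,BAK,600,114,0,0,114
8,Lung,BAX,600,114,0,0,114
9,Lung,H&E,600,114,0,0,114
10,Lung,CB1,600,114,0,0,114
11,Lung,Negative Control,600,114,0,0,114
12,Lung,NOXA,600,114,0,0,114
13,Lung,BAX,600,144,4,0,140
14,Lung,H&E,600,144,1,0,143
15,Lung,CB1,600,144,2,0,142
16,Lung,Negative Control,600,144,4,0,140
17,Lung,NOXA,600,144,1,0,143
18,Brain,unknown,1200,90,10,0,80
19,unknown,unknown,500,360,57,0,303
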