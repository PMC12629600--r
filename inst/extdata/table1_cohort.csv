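participant_id,group,age,sex,autoantibodies,ogtt,t1d_stage,contributed_binder
1,stage1,29,F,GAD65;ICA;ZNT8,Normal,1,FALSE
2,stage1,17,F,GAD65,Normal,1,FALSE
3,stage1,12,M,MIAA;GAD65;IA2;ZNT8,Normal,1,TRUE
4,stage1,19,F,GAD65;IA2;ICA;ZNT8,Normal,1,FALSE
5,stage1,21,M,GAD65;ZNT8,Normal,1,FALSE
6,stage1,18,M,MIAA;GAD65;ZNT8,Normal,1,FALSE
7,stage1,8,M,GAD65;IA2;ICA;ZNT8,Normal,1,FALSE
8,stage1,8,F,MIAA;GAD65;ICA;ZNT8,Normal,1,TRUE
9,stage1,41,F,GAD65;ICA,Normal,1,FALSE
10,healthy,13,F,None,ND,non_diabetic,FALSE
11,healthy,17,F,None,ND,non_diabetic,FALSE
12,healthy,9,M,None,ND,non_diabetic,FALSE
13,healthy,17,F,None,ND,non_diabetic,FALSE
14,healthy,17,F,ND,ND,non_diabetic,FALSE
15,healthy,14,M,ND,ND,non_diabetic,FALSE
16,healthy,46,M,ND,ND,non_diabetic,FALSE
17,healthy,48,F,ND,ND,non_diabetic,FALSE
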