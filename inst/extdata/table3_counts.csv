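drug,dimension,level,count,pct_printed
SEM,total,total,21012,
ALB,total,total,384,
DUL,total,total,17332,
EXE,total,total,12926,
LIR,total,total,18149,
LIX,total,total,412,
TIR,total,total,2333,
ALL_OTHER,total,total,51536,
SEM,age,NS,7942,37.8
ALB,age,NS,148,38.5
DUL,age,NS,5476,31.6
EXE,age,NS,4160,32.2
LIR,age,NS,6668,36.7
LIX,age,NS,105,25.5
TIR,age,NS,1138,48.8
ALL_OTHER,age,NS,17695,34.3
SEM,age,m0_1,1,0
ALB,age,m0_1,0,0
DUL,age,m0_1,1,0
EXE,age,m0_1,6,0
LIR,age,m0_1,4,0
LIX,age,m0_1,0,0
TIR,age,m0_1,0,0
ALL_OTHER,age,m0_1,11,0
SEM,age,m2_y2,2,0
ALB,age,m2_y2,0,0
DUL,age,m2_y2,3,0
EXE,age,m2_y2,1,0
LIR,age,m2_y2,4,0
LIX,age,m2_y2,0,0
TIR,age,m2_y2,0,0
ALL_OTHER,age,m2_y2,8,0
SEM,age,y3_11,9,0
ALB,age,y3_11,0,0
DUL,age,y3_11,2,0
EXE,age,y3_11,1,0
LIR,age,y3_11,9,0
LIX,age,y3_11,0,0
TIR,age,y3_11,0,0
ALL_OTHER,age,y3_11,12,0
SEM,age,y12_17,23,0.1
ALB,age,y12_17,0,0
DUL,age,y12_17,6,0
EXE,age,y12_17,6,0
LIR,age,y12_17,64,0.4
LIX,age,y12_17,0,0
TIR,age,y12_17,2,0
ALL_OTHER,age,y12_17,78,0.2
SEM,age,y18_64,8345,39.7
ALB,age,y18_64,162,42.2
DUL,age,y18_64,6576,37.9
EXE,age,y18_64,5519,42.7
LIR,age,y18_64,8236,45.4
LIX,age,y18_64,186,45.1
TIR,age,y18_64,863,37
ALL_OTHER,age,y18_64,21542,41.8
SEM,age,y65_85,4546,21.6
ALB,age,y65_85,72,18.8
DUL,age,y65_85,4951,28.6
EXE,age,y65_85,3153,24.4
LIR,age,y65_85,3104,17.1
LIX,age,y65_85,118,28.6
TIR,age,y65_85,307,13.2
ALL_OTHER,age,y65_85,11705,22.7
SEM,age,over85,144,0.7
ALB,age,over85,2,0.5
DUL,age,over85,317,1.8
EXE,age,over85,80,0.6
LIR,age,over85,60,0.3
LIX,age,over85,3,0.7
TIR,age,over85,23,1
ALL_OTHER,age,over85,485,0.9
SEM,sex,female,12122,57.7
ALB,sex,female,211,54.9
DUL,sex,female,8443,48.7
EXE,sex,female,6741,52.2
LIR,sex,female,10851,59.8
LIX,sex,female,210,51
TIR,sex,female,1180,50.6
ALL_OTHER,sex,female,27636,53.6
SEM,sex,male,8206,39.1
ALB,sex,male,158,41.1
DUL,sex,male,7676,44.3
EXE,sex,male,5825,45.1
LIR,sex,male,6189,34.1
LIX,sex,male,169,41
TIR,sex,male,685,29.4
ALL_OTHER,sex,male,20702,40.2
SEM,sex,NS,684,3.3
ALB,sex,NS,15,3.9
DUL,sex,NS,1213,7
EXE,sex,NS,360,2.8
LIR,sex,NS,1109,6.1
LIX,sex,NS,33,8
TIR,sex,NS,468,20.1
ALL_OTHER,sex,NS,3198,6.2
SEM,region,EEA,11060,52.6
ALB,region,EEA,12,3.1
DUL,region,EEA,8864,51.1
EXE,region,EEA,3226,25
LIR,region,EEA,7309,40.3
LIX,region,EEA,265,64.3
TIR,region,EEA,115,4.9
ALL_OTHER,region,EEA,19791,38.4
SEM,region,non_EEA,9952,47.4
ALB,region,non_EEA,372,96.9
DUL,region,non_EEA,8468,48.9
EXE,region,non_EEA,9700,75
LIR,region,non_EEA,10839,59.7
LIX,region,non_EEA,147,35.7
TIR,region,non_EEA,2218,95.1
ALL_OTHER,region,non_EEA,31744,61.6
SEM,region,NS,0,0
ALB,region,NS,0,0
DUL,region,NS,0,0
EXE,region,NS,0,0
LIR,region,NS,1,0
LIX,region,NS,0,0
TIR,region,NS,0,0
ALL_OTHER,region,NS,1,0
SEM,reporter,HP,12877,61.3
ALB,reporter,HP,175,45.6
DUL,reporter,HP,11001,63.5
EXE,reporter,HP,8751,67.7
LIR,reporter,HP,12316,67.9
LIX,reporter,HP,333,80.8
TIR,reporter,HP,1470,63
ALL_OTHER,reporter,HP,34046,66.1
SEM,reporter,NHP,8135,38.7
ALB,reporter,NHP,209,54.4
DUL,reporter,NHP,6331,36.5
EXE,reporter,NHP,4168,32.2
LIR,reporter,NHP,5832,32.1
LIX,reporter,NHP,79,19.2
TIR,reporter,NHP,863,37
ALL_OTHER,reporter,NHP,17482,33.9
SEM,reporter,NS,0,0
ALB,reporter,NS,0,0
DUL,reporter,NS,0,0
EXE,reporter,NS,7,0.1
LIR,reporter,NS,1,0
LIX,reporter,NS,0,0
TIR,reporter,NS,0,0
ALL_OTHER,reporter,NS,8,0
SEM,seriousness,serious,12029,57.2
ALB,seriousness,serious,379,98.7
DUL,seriousness,serious,10281,59.3
EXE,seriousness,serious,11540,89.3
LIR,seriousness,serious,13509,74.4
LIX,seriousness,serious,293,71.1
TIR,seriousness,serious,2213,94.9
ALL_OTHER,seriousness,serious,38215,74.2
SEM,seriousness,non_serious,8983,42.8
ALB,seriousness,non_serious,5,1.3
DUL,seriousness,non_serious,7051,40.7
EXE,seriousness,non_serious,1383,10.7
LIR,seriousness,non_serious,4637,25.5
LIX,seriousness,non_serious,119,28.9
TIR,seriousness,non_serious,120,5.1
ALL_OTHER,seriousness,non_serious,13315,25.8
SEM,seriousness,NS,0,0
ALB,seriousness,NS,0,0
DUL,seriousness,NS,0,0
EXE,seriousness,NS,3,0
LIR,seriousness,NS,3,0
LIX,seriousness,NS,0,0
TIR,seriousness,NS,0,0
ALL_OTHER,seriousness,NS,6,0
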