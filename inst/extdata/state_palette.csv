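state,color
SUD,#8C510A
SZ,#762A83
BD,#9970AB
SRD,#2166AC
OMD,#4393C3
AND,#92C5DE
OCD,#1B7837
SAD,#5AAE61
SOM,#ACD39E
ED,#D6604D
PD,#B2182B
ID,#F4A582
ODD,#FDDBC7
ASD,#E08214
ADHD,#FDB863
CD,#8073AC
AD,#B35806
TD,#35978F
OTHER,#BABABA
DEAD,#1A1A1A
EMIGRATED,#878787
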