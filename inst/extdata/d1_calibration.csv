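category,pct_female,pct_male,onset_mean_female,onset_mean_male,onset_sd
SUD,2.0,1.8,15.6,16.2,1.2
SZ,2.2,1.3,16.0,15.8,1.5
BD,0.21,0.14,16.0,16.0,1.2
SRD,8.0,3.0,15.3,14.8,1.8
OMD,0.6,0.3,15.5,15.0,1.8
AND,8.5,6.0,11.5,10.5,3.0
OCD,3.0,2.5,13.0,12.2,2.5
SAD,23.0,10.0,14.5,13.5,2.8
SOM,3.0,1.5,13.5,12.8,2.5
ED,11.9,1.0,15.0,13.5,1.8
PD,1.5,0.5,16.8,16.5,0.8
ID,2.2,4.0,9.5,8.8,3.0
ODD,5.0,6.2,8.8,8.2,2.8
ASD,7.0,19.3,8.8,8.1,3.0
ADHD,9.7,24.7,10.5,9.5,2.8
CD,2.0,4.0,12.5,11.5,2.8
AD,2.5,3.0,8.9,8.3,3.0
TD,1.5,4.0,10.5,10.5,2.5
OTHER,6.19,6.76,11.0,10.0,3.5
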