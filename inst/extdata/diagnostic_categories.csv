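category,include,exclude
SUD,F10;F11;F12;F13;F14;F15;F16;F17;F18;F19,
SZ,F20;F21;F22;F23;F24;F25;F26;F27;F28;F29,
BD,F30;F31,
SRD,F32;F33,
OMD,F34;F35;F36;F37;F38;F39,
AND,F40;F41;F93,
OCD,F42,
SAD,F43,
SOM,F44;F45;F46;F47;F48,
ED,F50,
PD,F60;F61;F62;F63;F64;F65;F66;F67;F68;F69,
ID,F70;F71;F72;F73;F74;F75;F76;F77;F78;F79,
ODD,F80;F81;F82;F83,
ASD,F84,F84.2;F84.3;F84.4
ADHD,F90;F98.8,
CD,F91,
AD,F94,F94.0
TD,F95,
OTHER,F51;F52;F53;F54;F55;F56;F57;F58;F59;F84.2;F84.3;F84.4;F88;F89;F92;F98.0;F98.1;F98.2;F98.3;F98.4;F98.5;F98.6;F98.9;F99,
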