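resid,tds
ALA,0
GLY,0
PRO,0
SER,0.651
CYS,0.651
THR,0.651
VAL,0.651
LEU,1.303
ILE,1.303
ASP,1.303
ASN,1.303
PHE,1.303
TYR,1.303
TRP,1.303
HIS,1.303
MET,1.303
GLU,1.954
GLN,1.954
LYS,2.606
ARG,2.606
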