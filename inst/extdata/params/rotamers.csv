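resid,rot,chi1,chi2,chi3,chi4
ALA,1,NA,NA,NA,NA
ARG,1,-60,180,180,180
ARG,2,180,180,180,180
ARG,3,60,180,180,180
ARG,4,-60,65,180,180
ARG,5,180,65,180,180
ARG,6,60,65,180,180
ARG,7,-60,-65,180,180
ARG,8,180,-65,180,180
ARG,9,60,-65,180,180
ASN,1,-60,180,NA,NA
ASN,2,180,180,NA,NA
ASN,3,60,180,NA,NA
ASN,4,-60,65,NA,NA
ASN,5,180,65,NA,NA
ASN,6,60,65,NA,NA
ASN,7,-60,-65,NA,NA
ASN,8,180,-65,NA,NA
ASN,9,60,-65,NA,NA
ASP,1,-60,180,NA,NA
ASP,2,180,180,NA,NA
ASP,3,60,180,NA,NA
ASP,4,-60,65,NA,NA
ASP,5,180,65,NA,NA
ASP,6,60,65,NA,NA
ASP,7,-60,-65,NA,NA
ASP,8,180,-65,NA,NA
ASP,9,60,-65,NA,NA
CYS,1,-60,NA,NA,NA
CYS,2,180,NA,NA,NA
CYS,3,60,NA,NA,NA
GLN,1,-60,180,180,NA
GLN,2,180,180,180,NA
GLN,3,60,180,180,NA
GLN,4,-60,65,180,NA
GLN,5,180,65,180,NA
GLN,6,60,65,180,NA
GLN,7,-60,-65,180,NA
GLN,8,180,-65,180,NA
GLN,9,60,-65,180,NA
GLU,1,-60,180,180,NA
GLU,2,180,180,180,NA
GLU,3,60,180,180,NA
GLU,4,-60,65,180,NA
GLU,5,180,65,180,NA
GLU,6,60,65,180,NA
GLU,7,-60,-65,180,NA
GLU,8,180,-65,180,NA
GLU,9,60,-65,180,NA
GLY,1,NA,NA,NA,NA
HIS,1,-60,180,NA,NA
HIS,2,180,180,NA,NA
HIS,3,60,180,NA,NA
HIS,4,-60,65,NA,NA
HIS,5,180,65,NA,NA
HIS,6,60,65,NA,NA
HIS,7,-60,-65,NA,NA
HIS,8,180,-65,NA,NA
HIS,9,60,-65,NA,NA
ILE,1,-60,180,NA,NA
ILE,2,180,180,NA,NA
ILE,3,60,180,NA,NA
ILE,4,-60,65,NA,NA
ILE,5,180,65,NA,NA
ILE,6,60,65,NA,NA
ILE,7,-60,-65,NA,NA
ILE,8,180,-65,NA,NA
ILE,9,60,-65,NA,NA
LEU,1,-60,180,NA,NA
LEU,2,180,180,NA,NA
LEU,3,60,180,NA,NA
LEU,4,-60,65,NA,NA
LEU,5,180,65,NA,NA
LEU,6,60,65,NA,NA
LEU,7,-60,-65,NA,NA
LEU,8,180,-65,NA,NA
LEU,9,60,-65,NA,NA
LYS,1,-60,180,180,180
LYS,2,180,180,180,180
LYS,3,60,180,180,180
LYS,4,-60,65,180,180
LYS,5,180,65,180,180
LYS,6,60,65,180,180
LYS,7,-60,-65,180,180
LYS,8,180,-65,180,180
LYS,9,60,-65,180,180
MET,1,-60,180,180,NA
MET,2,180,180,180,NA
MET,3,60,180,180,NA
MET,4,-60,65,180,NA
MET,5,180,65,180,NA
MET,6,60,65,180,NA
MET,7,-60,-65,180,NA
MET,8,180,-65,180,NA
MET,9,60,-65,180,NA
PHE,1,-60,180,NA,NA
PHE,2,180,180,NA,NA
PHE,3,60,180,NA,NA
PHE,4,-60,65,NA,NA
PHE,5,180,65,NA,NA
PHE,6,60,65,NA,NA
PHE,7,-60,-65,NA,NA
PHE,8,180,-65,NA,NA
PHE,9,60,-65,NA,NA
PRO,1,30,-35,NA,NA
SER,1,-60,NA,NA,NA
SER,2,180,NA,NA,NA
SER,3,60,NA,NA,NA
THR,1,-60,NA,NA,NA
THR,2,180,NA,NA,NA
THR,3,60,NA,NA,NA
TRP,1,-60,180,NA,NA
TRP,2,180,180,NA,NA
TRP,3,60,180,NA,NA
TRP,4,-60,65,NA,NA
TRP,5,180,65,NA,NA
TRP,6,60,65,NA,NA
TRP,7,-60,-65,NA,NA
TRP,8,180,-65,NA,NA
TRP,9,60,-65,NA,NA
TYR,1,-60,180,NA,NA
TYR,2,180,180,NA,NA
TYR,3,60,180,NA,NA
TYR,4,-60,65,NA,NA
TYR,5,180,65,NA,NA
TYR,6,60,65,NA,NA
TYR,7,-60,-65,NA,NA
TYR,8,180,-65,NA,NA
TYR,9,60,-65,NA,NA
VAL,1,-60,NA,NA,NA
VAL,2,180,NA,NA,NA
VAL,3,60,NA,NA,NA
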