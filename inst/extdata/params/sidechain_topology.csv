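resid,atom,p1,p2,p3,b,ang,dref,doff
SER,OG,CB,CA,N,1.42,110.5,chi1,0
CYS,SG,CB,CA,N,1.81,114,chi1,0
THR,OG1,CB,CA,N,1.43,109.5,chi1,0
THR,CG2,CB,CA,N,1.52,110.5,chi1,-120
VAL,CG1,CB,CA,N,1.52,110.5,chi1,0
VAL,CG2,CB,CA,N,1.52,110.5,chi1,120
LEU,CG,CB,CA,N,1.53,116.3,chi1,0
LEU,CD1,CG,CB,CA,1.52,110.5,chi2,0
LEU,CD2,CG,CB,CA,1.52,110.5,chi2,120
ILE,CG1,CB,CA,N,1.53,110.4,chi1,0
ILE,CG2,CB,CA,N,1.52,110.5,chi1,-120
ILE,CD1,CG1,CB,CA,1.52,113.8,chi2,0
PRO,CG,CB,CA,N,1.49,104.5,chi1,0
PRO,CD,CG,CB,CA,1.5,105.5,chi2,0
MET,CG,CB,CA,N,1.52,114.1,chi1,0
MET,SD,CG,CB,CA,1.8,112.7,chi2,0
MET,CE,SD,CG,CB,1.79,100.2,chi3,0
PHE,CG,CB,CA,N,1.5,113.8,chi1,0
PHE,CD1,CG,CB,CA,1.39,120.3,chi2,0
PHE,CD2,CG,CB,CA,1.39,120.3,chi2,180
PHE,CE1,CD1,CG,CB,1.39,120,fix,180
PHE,CE2,CD2,CG,CB,1.39,120,fix,180
PHE,CZ,CE1,CD1,CG,1.39,120,fix,0
TYR,CG,CB,CA,N,1.51,113.9,chi1,0
TYR,CD1,CG,CB,CA,1.39,120.3,chi2,0
TYR,CD2,CG,CB,CA,1.39,120.3,chi2,180
TYR,CE1,CD1,CG,CB,1.39,120,fix,180
TYR,CE2,CD2,CG,CB,1.39,120,fix,180
TYR,CZ,CE1,CD1,CG,1.39,120,fix,0
TYR,OH,CZ,CE1,CD1,1.38,120,fix,180
TRP,CG,CB,CA,N,1.5,114,chi1,0
TRP,CD1,CG,CB,CA,1.37,126.9,chi2,0
TRP,CD2,CG,CB,CA,1.43,126.7,chi2,180
TRP,NE1,CD1,CG,CB,1.38,110.1,fix,180
TRP,CE2,NE1,CD1,CG,1.37,109,fix,0
TRP,CE3,CD2,CG,CD1,1.4,133.9,fix,180
TRP,CZ2,CE2,NE1,CD1,1.4,130.4,fix,180
TRP,CZ3,CE3,CD2,CG,1.39,118.8,fix,180
TRP,CH2,CZ2,CE2,NE1,1.37,117.5,fix,180
ASP,CG,CB,CA,N,1.52,113.1,chi1,0
ASP,OD1,CG,CB,CA,1.25,118.2,chi2,0
ASP,OD2,CG,CB,CA,1.25,118.2,chi2,180
ASN,CG,CB,CA,N,1.52,112.7,chi1,0
ASN,OD1,CG,CB,CA,1.23,120.9,chi2,0
ASN,ND2,CG,CB,CA,1.33,116.5,chi2,180
GLU,CG,CB,CA,N,1.53,114.1,chi1,0
GLU,CD,CG,CB,CA,1.52,112.6,chi2,0
GLU,OE1,CD,CG,CB,1.25,118.2,chi3,0
GLU,OE2,CD,CG,CB,1.25,118.2,chi3,180
GLN,CG,CB,CA,N,1.53,114.1,chi1,0
GLN,CD,CG,CB,CA,1.52,112.6,chi2,0
GLN,OE1,CD,CG,CB,1.23,120.9,chi3,0
GLN,NE2,CD,CG,CB,1.33,116.5,chi3,180
LYS,CG,CB,CA,N,1.52,114.1,chi1,0
LYS,CD,CG,CB,CA,1.52,111.3,chi2,0
LYS,CE,CD,CG,CB,1.52,111.3,chi3,0
LYS,NZ,CE,CD,CG,1.49,112,chi4,0
ARG,CG,CB,CA,N,1.52,114.1,chi1,0
ARG,CD,CG,CB,CA,1.52,111.3,chi2,0
ARG,NE,CD,CG,CB,1.46,112,chi3,0
ARG,CZ,NE,CD,CG,1.33,124.2,chi4,0
ARG,NH1,CZ,NE,CD,1.33,120,fix,0
ARG,NH2,CZ,NE,CD,1.33,120,fix,180
HIS,CG,CB,CA,N,1.49,113.8,chi1,0
HIS,ND1,CG,CB,CA,1.38,122.7,chi2,0
HIS,CD2,CG,CB,CA,1.36,129.1,chi2,180
HIS,CE1,ND1,CG,CB,1.32,109.3,fix,180
HIS,NE2,CD2,CG,CB,1.37,107.2,fix,180
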