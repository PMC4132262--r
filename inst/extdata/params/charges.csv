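resid,atom,charge
ALL,N,-0.3
ALL,CA,0.3
ALL,C,0.55
ALL,O,-0.55
SER,CB,0.25
SER,OG,-0.25
THR,CB,0.25
THR,OG1,-0.25
CYS,CB,0.1
CYS,SG,-0.1
TYR,CZ,0.25
TYR,OH,-0.25
ASN,CB,0.3
ASN,CG,0.55
ASN,OD1,-0.55
ASN,ND2,-0.3
GLN,CG,0.3
GLN,CD,0.55
GLN,OE1,-0.55
GLN,NE2,-0.3
ASP,CB,-0.2
ASP,CG,0.3
ASP,OD1,-0.55
ASP,OD2,-0.55
GLU,CG,-0.2
GLU,CD,0.3
GLU,OE1,-0.55
GLU,OE2,-0.55
LYS,CE,0.25
LYS,NZ,0.75
ARG,NE,-0.4
ARG,CZ,0.6
ARG,NH1,0.4
ARG,NH2,0.4
HIS,CG,0.175
HIS,ND1,-0.35
HIS,CE1,0.35
HIS,NE2,-0.35
HIS,CD2,0.175
TRP,CD1,0.15
TRP,NE1,-0.3
TRP,CE2,0.15
MET,CG,0.05
MET,SD,-0.1
MET,CE,0.05
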