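pos,A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y
P1,0,0,-1,-1,2,0,0,2,-1,2,2,0,0,0,-1,0,0,2,2,2
P2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
P3,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
P4,0,0,-1,-1,1,0,0,1,-1,1,1,0,0,0,-1,0,0,1,1,1
P5,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
P6,1,0,0,0,0,1,0,0,0,0,0,0,1,0,0,1,1,0,0,0
P7,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
P8,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
P9,0,0,-1,-1,1.5,0,0,1.5,-1,1.5,1.5,0,0,0,-1,0,0,1.5,1.5,1.5
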