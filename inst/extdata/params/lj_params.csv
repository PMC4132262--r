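element,eps,rmin
C,0.1,1.9
N,0.17,1.8
O,0.21,1.7
S,0.3,2
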