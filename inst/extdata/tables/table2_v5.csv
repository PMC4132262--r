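mutation,location,ddg_parental,ddg_model,direction
LC:K24R,CDR L1,-0.21,-0.17,humanizing
LC:S56T,CDR L2,-0.05,0.04,humanizing
LC:V58I,Framework,-0.64,0.01,humanizing
HC:I20L,Framework,0.43,-0.86,humanizing
HC:A62S,CDR H2,-0.24,-0.50,humanizing
HC:F63V,CDR H2,1.91,1.80,humanizing
HC:M64K,CDR H2,0.10,-0.23,humanizing
HC:S65G,CDR H2,0.82,1.10,humanizing
HC:M89V,Framework,-0.50,-0.29,humanizing
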