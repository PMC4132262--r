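mutation,location
HC:A62S,CDR H2
HC:F63V,CDR H2
HC:M64K,CDR H2
HC:S65G,CDR H2
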