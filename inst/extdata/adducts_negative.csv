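name,mass_shift,charge,multiplier
M-H,-1.00727646688,-1,1
M+Cl,34.96940,-1,1
M+FA-H,44.99820,-1,1
2M-H,-1.00727646688,-1,2
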