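name,mass_shift,charge,multiplier
M+H,1.00727646688,1,1
M+Na,22.98922,1,1
M+K,38.96316,1,1
M+NH4,18.03383,1,1
2M+H,1.00727646688,1,2
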