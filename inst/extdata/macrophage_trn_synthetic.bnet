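# synthetic macrophage polarization TRN; cytokine/hypoxia inputs held (identity rules)
targets, factors
STAT1, IFNG & !STAT6
STAT3, (IL10 | IL6 | TGFB) & !SOCS3
STAT6, IL4 | PPARG | KLF4
NFKB, (TNFA | IL1B | GMCSF) & !STAT6
AP1, (IL6 | IL1B) & !(STAT6 | PPARG)
SOCS3, STAT1 | NFKB | STAT3
PPARG, HIF1A
KLF4, HIF1A
HIF1A, HIF1A
IFNG, IFNG
GMCSF, GMCSF
IL4, IL4
IL6, IL6
IL10, IL10
IL1B, IL1B
TNFA, TNFA
TGFB, TGFB
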