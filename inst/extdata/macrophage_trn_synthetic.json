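{
  "nodes": ["STAT1", "STAT3", "STAT6", "NFKB", "AP1", "SOCS3", "PPARG", "KLF4", "HIF1A", "IFNG", "GMCSF", "IL4", "IL6", "IL10", "IL1B", "TNFA", "TGFB"],
  "rules": {
    "STAT1": "IFNG & !STAT6",
    "STAT3": "(IL10 | IL6 | TGFB) & !SOCS3",
    "STAT6": "IL4 | PPARG | KLF4",
    "NFKB": "(TNFA | IL1B | GMCSF) & !STAT6",
    "AP1": "(IL6 | IL1B) & !(STAT6 | PPARG)",
    "SOCS3": "STAT1 | NFKB | STAT3",
    "PPARG": "HIF1A",
    "KLF4": "HIF1A"
  },
  "inputs": {
    "HIF1A": "hold",
    "IFNG": "hold",
    "GMCSF": "hold",
    "IL4": "hold",
    "IL6": "hold",
    "IL10": "hold",
    "IL1B": "hold",
    "TNFA": "hold",
    "TGFB": "hold"
  },
  "metadata": "synthetic macrophage polarization TRN; cytokine/hypoxia inputs held (identity rules)"
}
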