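{
  "n_nodes": 17,
  "n_attractors": 512,
  "periods": {
    "1": 169,
    "4": 343
  },
  "basin_sum": 131072
}
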