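{
  "n_probes": 400,
  "fraction_in_repeats": 0.9,
  "group_sizes": {"control": 12, "heterogeneous": 12, "variantA": 5, "variantB": 8},
  "n_gene_pool": 80,
  "n_expression_studies": 3
}
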