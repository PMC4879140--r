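{
  "accuracy_2feature_hbo.tsv": {"n_rows": 15, "sum": 7500.43},
  "accuracy_2feature_hbr.tsv": {"n_rows": 15, "sum": 7546.43},
  "accuracy_3feature_hbo.tsv": {"n_rows": 20, "sum": 11125.41},
  "accuracy_3feature_hbr.tsv": {"n_rows": 20, "sum": 11098.36}
}
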