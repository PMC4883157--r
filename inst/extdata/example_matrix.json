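{
  "matrix": [[80, 10], [0, 10]],
  "row_labels": ["H", "P"],
  "col_labels": ["H", "P"]
}
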