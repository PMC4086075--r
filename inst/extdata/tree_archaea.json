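{
  "domain": "archaea",
  "root": "n1",
  "nodes": [
    {"id": "n1", "left": "cytosol", "right": "n2"},
    {"id": "n2", "left": "plasma membrane", "right": "extra-cellular"}
  ]
}
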