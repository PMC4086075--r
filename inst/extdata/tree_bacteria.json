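{
  "domain": "bacteria",
  "root": "n1",
  "nodes": [
    {"id": "n1", "left": "n2", "right": "n3"},
    {"id": "n2", "left": "cytosol", "right": "plasma membrane"},
    {"id": "n3", "left": "periplasmic space", "right": "n4"},
    {"id": "n4", "left": "outer membrane", "right": "n5"},
    {"id": "n5", "left": "fimbrium", "right": "extra-cellular"}
  ]
}
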