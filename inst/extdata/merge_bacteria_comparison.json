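{
  "domain": "bacteria",
  "comment": "cross-method comparison merge: secreted and fimbrium proteins pooled into one class",
  "map": {
    "cytosol": "cytosol",
    "plasma membrane": "plasma membrane",
    "periplasmic space": "periplasmic space",
    "outer membrane": "outer membrane",
    "fimbrium": "extra-cellular",
    "extra-cellular": "extra-cellular"
  }
}
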