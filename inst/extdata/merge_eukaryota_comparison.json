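{
  "domain": "eukaryota",
  "comment": "cross-method comparison merge: membrane classes other than the cell membrane are folded into their compartment, and plastid/chloroplast are pooled",
  "map": {
    "chloroplast": "plastid",
    "chloroplast membrane": "plastid",
    "cytosol": "cytosol",
    "endoplasmic reticulum": "endoplasmic reticulum",
    "endoplasmic reticulum membrane": "endoplasmic reticulum",
    "extra-cellular": "extra-cellular",
    "golgi apparatus": "golgi apparatus",
    "golgi apparatus membrane": "golgi apparatus",
    "mitochondrion": "mitochondrion",
    "mitochondrion membrane": "mitochondrion",
    "nucleus": "nucleus",
    "nucleus membrane": "nucleus",
    "peroxisome": "peroxisome",
    "peroxisome membrane": "peroxisome",
    "plasma membrane": "plasma membrane",
    "plastid": "plastid",
    "vacuole": "vacuole",
    "vacuole membrane": "vacuole"
  }
}
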