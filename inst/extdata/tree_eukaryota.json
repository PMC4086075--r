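{
  "domain": "eukaryota",
  "root": "n1",
  "nodes": [
    {"id": "n1", "left": "n2", "right": "n3"},
    {"id": "n2", "left": "n4", "right": "n5"},
    {"id": "n4", "left": "cytosol", "right": "n6"},
    {"id": "n6", "left": "nucleus", "right": "nucleus membrane"},
    {"id": "n5", "left": "n7", "right": "n8"},
    {"id": "n7", "left": "mitochondrion", "right": "mitochondrion membrane"},
    {"id": "n8", "left": "n9", "right": "n10"},
    {"id": "n9", "left": "peroxisome", "right": "peroxisome membrane"},
    {"id": "n10", "left": "plastid", "right": "n11"},
    {"id": "n11", "left": "chloroplast", "right": "chloroplast membrane"},
    {"id": "n3", "left": "n12", "right": "n13"},
    {"id": "n12", "left": "n14", "right": "n15"},
    {"id": "n14", "left": "endoplasmic reticulum", "right": "endoplasmic reticulum membrane"},
    {"id": "n15", "left": "golgi apparatus", "right": "golgi apparatus membrane"},
    {"id": "n13", "left": "n16", "right": "n17"},
    {"id": "n16", "left": "vacuole", "right": "vacuole membrane"},
    {"id": "n17", "left": "plasma membrane", "right": "extra-cellular"}
  ]
}
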