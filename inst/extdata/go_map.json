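{
  "cytosol": [{"name": "cytosol", "go_id": "GO:0005829"}],
  "nucleus": [{"name": "nucleus", "go_id": "GO:0005634"}],
  "nucleus membrane": [{"name": "nuclear membrane", "go_id": "GO:0031965"}],
  "mitochondrion": [{"name": "mitochondrion", "go_id": "GO:0005739"}],
  "mitochondrion membrane": [{"name": "mitochondrial membrane", "go_id": "GO:0031966"}],
  "peroxisome": [{"name": "peroxisome", "go_id": "GO:0005777"}],
  "peroxisome membrane": [{"name": "peroxisomal membrane", "go_id": "GO:0005778"}],
  "plastid": [{"name": "plastid", "go_id": "GO:0009536"}],
  "chloroplast": [{"name": "chloroplast", "go_id": "GO:0009507"}],
  "chloroplast membrane": [{"name": "chloroplast membrane", "go_id": "GO:0031969"}],
  "endoplasmic reticulum": [{"name": "endoplasmic reticulum", "go_id": "GO:0005783"}],
  "endoplasmic reticulum membrane": [{"name": "endoplasmic reticulum membrane", "go_id": "GO:0005789"}],
  "golgi apparatus": [{"name": "Golgi apparatus", "go_id": "GO:0005794"}],
  "golgi apparatus membrane": [{"name": "Golgi membrane", "go_id": "GO:0000139"}],
  "vacuole": [{"name": "vacuole", "go_id": "GO:0005773"}],
  "vacuole membrane": [{"name": "vacuolar membrane", "go_id": "GO:0005774"}],
  "plasma membrane": [{"name": "plasma membrane", "go_id": "GO:0005886"}],
  "extra-cellular": [{"name": "extracellular region", "go_id": "GO:0005576"}],
  "periplasmic space": [{"name": "periplasmic space", "go_id": "GO:0042597"}],
  "outer membrane": [{"name": "outer membrane", "go_id": "GO:0019867"}],
  "fimbrium": [{"name": "pilus", "go_id": "GO:0009289"}]
}
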