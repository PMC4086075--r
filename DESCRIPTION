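Package: profloc
Title: Protein Subcellular Localization by Profile-Kernel SVM Trees and
    Homology Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of proteins in 18
    eukaryotic, 6 bacterial or 3 archaeal compartment classes. Two routes
    are combined: annotation transfer from the closest experimentally
    annotated homolog (gated on alignment E-value, with a reliability
    index derived from percentage sequence identity), and a de novo
    predictor consisting of a binary decision tree of support vector
    machines over a sparse profile k-mer string kernel. Includes parsers
    for FASTA, NCBI ASCII PSSM and tabular BLAST hits, the full
    evaluation machinery (per-class accuracy and coverage, n-state
    accuracy, bootstrap standard errors, reliability-accuracy-coverage
    curves), a synthetic benchmark generator with planted k-mer motifs
    and controlled-identity homolog pairs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    kernlab,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
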