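# Shared fixtures, built in code. Heavier objects (a trained toy model)
# are memoized so the suite builds them once.

.fixture_cache <- new.env(parent = emptyenv())

random_profile <- function(L, id = "p") {
  sc <- matrix(runif(L * 20, 0, score_ceiling()), L, 20)
  # guarantee every row has a score below the clamp ceiling
  sc[cbind(seq_len(L), sample.int(20, L, replace = TRUE))] <-
    runif(L, 0, 0.5)
  colnames(sc) <- aa_alphabet()
  structure(list(id = id, length = L, scores = sc, source = "FABRICATED"),
            class = "seq_profile")
}

random_record <- function(L, id = "r") {
  seq_records(id, "", paste(sample(aa_alphabet(), L, replace = TRUE),
                            collapse = ""))
}

# small archaeal scenario + trained tree, shared across tests
tiny_scenario <- function() {
  if (!exists("tiny", .fixture_cache)) {
    cfg <- scenario_config(domain = "archaea", n_per_class = 10,
                           n_queries_per_class = 6,
                           seq_len_range = c(60L, 90L),
                           homolog_fraction = 0.5, target_pide = 60,
                           seed = 11)
    ds <- make_dataset(cfg)
    params <- kernel_params(default_k("archaea"), 6.0)
    model <- train_tree(ds$profiles[ds$reference$id], ds$reference_db,
                        default_tree_spec("archaea"), params)
    assign("tiny", list(ds = ds, model = model, params = params),
           .fixture_cache)
  }
  get("tiny", .fixture_cache)
}

# minimal well-formed NCBI ASCII PSSM text for given percentage rows
# (list of numeric length-20 vectors in NCBI column order)
pssm_text <- function(pct_rows, residues = NULL) {
  ncbi <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (is.null(residues)) residues <- rep("A", length(pct_rows))
  header <- c("",
              "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
              paste(c("   ", ncbi, ncbi), collapse = "  "))
  rows <- vapply(seq_along(pct_rows), function(i) {
    paste(c(sprintf("%5d %s", i, residues[i]),
            sprintf("%3d", rep(0L, 20)),          # log-odds (ignored)
            sprintf("%4.0f", pct_rows[[i]]),      # percentages
            " 0.50", " 1.00"), collapse = " ")
  }, character(1))
  c(header, rows, "", "                      K         Lambda")
}

write_pssm_fixture <- function(pct_rows, residues = NULL) {
  f <- tempfile(fileext = ".pssm")
  writeLines(pssm_text(pct_rows, residues), f)
  f
}
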