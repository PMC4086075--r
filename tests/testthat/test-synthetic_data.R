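# The synthetic benchmark generator.

test_that("motifs are reproducible, distinct and well separated", {
  cfg <- scenario_config(domain = "archaea", motifs_per_class = 2,
                        motif_len = 6, seed = 1)
  m1 <- make_motifs(cfg)
  m2 <- make_motifs(cfg)
  expect_identical(m1, m2)
  expect_named(m1, domain_classes("archaea"))
  all_m <- unlist(m1)
  expect_equal(anyDuplicated(all_m), 0L)
  for (i in seq_along(all_m)) for (j in seq_len(i - 1))
    expect_gte(profloc:::hamming(all_m[i], all_m[j]), 2L)

  cfg2 <- scenario_config(domain = "archaea", motifs_per_class = 2,
                          motif_len = 6, seed = 2)
  expect_false(identical(make_motifs(cfg2), m1))

  # infeasible motif space
  cfg3 <- scenario_config(domain = "archaea", motifs_per_class = 300,
                          motif_len = 3, seed = 1)
  expect_error(make_motifs(cfg3), "motif space")
})

test_that("sampled sequences carry their class motifs", {
  cfg <- scenario_config(domain = "archaea", seq_len_range = c(60L, 60L),
                         motif_insertions_per_seq = 2, motif_len = 6,
                         seed = 4)
  motifs <- make_motifs(cfg)
  set.seed(8)
  rec <- sample_sequence("cytosol", motifs, cfg, id = "s1")
  expect_equal(nchar(rec$residues), 60L)
  found <- vapply(motifs[["cytosol"]], function(m)
    grepl(m, rec$residues, fixed = TRUE), logical(1))
  expect_gte(sum(found), 1L)   # at least one planted motif visible

  set.seed(8)
  rec2 <- sample_sequence("cytosol", motifs, cfg, id = "s1")
  expect_identical(rec, rec2)  # fixed draw state -> identical sequence
})

test_that("zero-probability background letters appear only inside motifs", {
  bg <- rep(1, 20)
  bg[match("W", aa_alphabet())] <- 0
  cfg <- scenario_config(domain = "archaea", seq_len_range = c(80L, 80L),
                         background = bg, motif_len = 6, seed = 5)
  motifs <- make_motifs(cfg)
  set.seed(5)
  rec <- sample_sequence("cytosol", motifs, cfg, id = "s")
  n_w <- lengths(regmatches(rec$residues, gregexpr("W", rec$residues)))
  # W can only arrive through the <= 2 planted motif copies
  expect_lte(n_w, 2L * sum(grepl("W", motifs[["cytosol"]])) * 6L)
})

test_that("make_homolog hits the target identity exactly at L = 100", {
  set.seed(6)
  rec <- random_record(100, "r")
  hm <- make_homolog(rec, 60)
  expect_equal(hm$realized_pide, 60)
  # independent position-wise identity count agrees
  expect_equal(pide_identity(rec$residues, hm$record$residues), 60)

  identical_copy <- make_homolog(rec, 100)
  expect_equal(identical_copy$realized_pide, 100)
  expect_equal(identical_copy$record$residues, rec$residues)

  expect_error(make_homolog(rec, 0), "target_pide")
})

test_that("every substituted position differs from the original letter", {
  set.seed(61)
  rec <- random_record(200, "r")
  hm <- make_homolog(rec, 40)
  a <- strsplit(rec$residues, "")[[1]]
  b <- strsplit(hm$record$residues, "")[[1]]
  expect_equal(sum(a == b), 80)   # exactly 120 substitutions
})

test_that("fabricated hits carry the documented E-value proxy", {
  q <- random_record(100, "q"); s <- random_record(100, "s")
  h60 <- fabricate_hit(q, s, 60)
  expect_equal(h60$evalue, 1e-12)
  expect_equal(h60$pide, 60)
  h0 <- fabricate_hit(q, s, 0)
  expect_equal(h0$evalue, 1)      # fails the default 1e-3 gate
  # round trip through the tabular format
  f <- tempfile()
  write_blast_tab(h60, f)
  back <- read_blast_tab(f)
  expect_equal(back$pide, 60)
  expect_equal(back$evalue, 1e-12)
})

test_that("make_dataset realizes the configured split exactly", {
  cfg <- scenario_config(domain = "bacteria", n_per_class = 4,
                         n_queries_per_class = 4,
                         homolog_fraction = 0.5, target_pide = 60,
                         seed = 9)
  ds <- make_dataset(cfg)
  expect_equal(nrow(ds$reference), 24L)
  expect_equal(nrow(ds$queries), 24L)
  expect_equal(sum(ds$split == "WITH_HIT"), 12L)
  expect_equal(sum(ds$split == "WITHOUT_HIT"), 12L)
  expect_setequal(names(ds$profiles), c(ds$reference$id, ds$queries$id))
  expect_equal(length(ds$truth), 48L)
  expect_setequal(ds$reference_db_ids, ds$reference$id)

  # homolog queries share their reference's class
  for (id in names(ds$split)[ds$split == "WITH_HIT"]) {
    hit <- ds$hits[ds$hits$query_id == id, ]
    expect_equal(db_class(ds$truth, id),
                 db_class(ds$reference_db, hit$subject_id))
  }
})

test_that("the split is exactly recoverable from hits + default policy", {
  cfg <- scenario_config(domain = "archaea", n_per_class = 5,
                         n_queries_per_class = 4,
                         homolog_fraction = 0.5, target_pide = 60,
                         seed = 10)
  ds <- make_dataset(cfg)
  for (id in ds$queries$id) {
    p <- predict_homology(id, ds$hits, ds$reference_db)
    expect_equal(!is.null(p), unname(ds$split[id] == "WITH_HIT"))
  }
})

test_that("homolog_fraction 0 routes everything de novo", {
  cfg <- scenario_config(domain = "archaea", n_per_class = 3,
                         n_queries_per_class = 3,
                         homolog_fraction = 0, seed = 12)
  ds <- make_dataset(cfg)
  expect_true(all(ds$split == "WITHOUT_HIT"))
  for (id in ds$queries$id)
    expect_null(predict_homology(id, ds$hits, ds$reference_db))
})

test_that("a fixed seed reproduces the dataset files byte for byte", {
  cfg <- scenario_config(domain = "archaea", n_per_class = 3,
                         n_queries_per_class = 2, seed = 14)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_dataset(make_dataset(cfg), d1)
  write_dataset(make_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("classes separate: centroid baseline beats chance, tree beats baseline", {
  # fresh (unmutated) queries so the generators' class signal is assessed
  cfg <- scenario_config(domain = "archaea", n_per_class = 15,
                         n_queries_per_class = 10,
                         homolog_fraction = 0, seed = 19)
  ds <- make_dataset(cfg)
  params <- kernel_params(default_k("archaea"), 6.0)
  classes <- domain_classes("archaea")
  ref_ids <- ds$reference$id
  ref_cls <- db_class(ds$reference_db, ref_ids)
  fvs <- lapply(ds$profiles, feature_map, params = params)
  # nearest-centroid on cosine similarity
  Kx <- kernel_cross(fvs[ds$queries$id], fvs[ref_ids])
  centroid_sim <- sapply(classes, function(cl)
    rowMeans(Kx[, ref_cls == cl, drop = FALSE]))
  baseline_pred <- classes[apply(centroid_sim, 1, which.max)]
  truth_cls <- db_class(ds$truth, ds$queries$id)
  baseline_acc <- mean(baseline_pred == truth_cls)
  expect_gt(baseline_acc, 1 / length(classes))   # beats chance

  model <- train_tree(fvs[ref_ids], ds$reference_db,
                      default_tree_spec("archaea"), params)
  preds <- predict_de_novo_batch(fvs[ds$queries$id], model)
  tree_acc <- mean(vapply(preds, `[[`, character(1), "loc_class") ==
                     truth_cls)
  expect_gte(tree_acc, baseline_acc)
})
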