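# The SVM decision tree: topology validation, node training, prediction.

test_that("shipped tree topologies match the domain class sets", {
  bac <- default_tree_spec("bacteria")
  expect_equal(nrow(bac$nodes), 5L)           # 6 leaves -> 5 internal
  expect_setequal(leaves_under(bac, bac$root), domain_classes("bacteria"))

  arc <- default_tree_spec("archaea")
  expect_equal(nrow(arc$nodes), 2L)
  expect_setequal(leaves_under(arc, arc$root), domain_classes("archaea"))

  euk <- default_tree_spec("eukaryota")
  expect_equal(nrow(euk$nodes), 17L)          # 18 leaves
  expect_setequal(leaves_under(euk, euk$root), domain_classes("eukaryota"))
})

test_that("tree validation rejects malformed or incomplete topologies", {
  # dropping fimbrium leaves the bacterial class set incomplete
  nodes <- data.frame(
    id = c("n1", "n2", "n3", "n4"),
    left = c("n2", "cytosol", "periplasmic space", "outer membrane"),
    right = c("n3", "plasma membrane", "n4", "extra-cellular"))
  expect_error(tree_spec("bacteria", nodes, "n1"), "fimbrium")

  # a child under two parents is not a tree
  nodes2 <- data.frame(id = c("n1", "n2"),
                       left = c("n2", "cytosol"),
                       right = c("cytosol", "extra-cellular"))
  expect_error(tree_spec("archaea", nodes2, "n1"), "two parents")

  f <- tempfile(fileext = ".json")
  writeLines('{"domain": "archaea"}', f)
  expect_error(load_tree_spec(f), "must have fields")
})

test_that("tree specs survive a JSON round trip", {
  spec <- default_tree_spec("bacteria")
  f <- tempfile(fileext = ".json")
  write_tree_spec(spec, f)
  back <- load_tree_spec(f)
  expect_equal(back$nodes, spec$nodes)
  expect_equal(back$root, spec$root)
})

test_that("train_node separates separable groups and calibrates", {
  # block kernel: high within-group, low across-group similarity
  n <- 8
  K <- matrix(0.1, 2 * n, 2 * n)
  K[1:n, 1:n] <- 0.9
  K[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0.9
  diag(K) <- 1
  ids <- paste0("e", 1:(2 * n))
  dimnames(K) <- list(ids, ids)
  labels <- stats::setNames(rep(c(-1, 1), each = n), ids)
  nm <- train_node(K, labels, C = 1, node_id = "n1")
  expect_s3_class(nm, "node_model")
  expect_lt(nm$platt_a, 0)
  dec <- vapply(ids, function(id)
    profloc:::node_decision(nm, K[id, ]), numeric(1))
  expect_true(all(sign(dec) == labels))      # 100% training accuracy

  expect_error(train_node(K, stats::setNames(rep(1, 2 * n), ids)),
               "single-class")
})

test_that("a zero decision value gives confidence exactly 0.5 when platt_b = 0", {
  nm <- structure(list(node_id = "n", support_ids = "a",
                       dual_coefs = 1, bias = 0,
                       platt_a = -2, platt_b = 0),
                  class = "node_model")
  expect_equal(profloc:::node_confidence(nm, 0), 0.5)
  expect_gt(profloc:::node_confidence(nm, 1), 0.5)
  expect_gt(profloc:::node_confidence(nm, -1), 0.5)  # max(p, 1-p)
})

test_that("train_tree recovers the training data on a separable scenario", {
  tiny <- tiny_scenario()
  model <- tiny$model
  expect_named(model$node_models, default_tree_spec("archaea")$nodes$id)
  preds <- lapply(tiny$ds$reference$id, function(id)
    predict_de_novo(tiny$ds$profiles[[id]], model, id = id))
  q <- qn(predictions_frame(preds), tiny$ds$truth)
  expect_equal(as.numeric(q), 100)
  expect_equal(attr(q, "n_states"), 3L)
})

test_that("train_tree validates its inputs", {
  tiny <- tiny_scenario()
  ds <- tiny$ds
  ref <- ds$profiles[ds$reference$id]
  spec <- default_tree_spec("archaea")
  # class with < 2 examples
  small_db <- annotation_db(ds$reference$id,
                            c("extra-cellular",
                              rep(c("cytosol", "plasma membrane"),
                                  length.out = nrow(ds$reference) - 1)),
                            "archaea")
  expect_error(train_tree(ref, small_db, spec, tiny$params),
               "fewer than 2")
  # unannotated id
  short_db <- annotation_db(ds$reference$id[-1],
                            db_class(ds$reference_db,
                                     ds$reference$id[-1]), "archaea")
  expect_error(train_tree(ref, short_db, spec, tiny$params),
               "unannotated")
})

test_that("training is deterministic: identical serialized models", {
  tiny <- tiny_scenario()
  ds <- tiny$ds
  ref <- ds$profiles[ds$reference$id]
  spec <- default_tree_spec("archaea")
  m1 <- train_tree(ref, ds$reference_db, spec, tiny$params)
  m2 <- train_tree(ref, ds$reference_db, spec, tiny$params)
  f1 <- tempfile(); f2 <- tempfile()
  write_model(m1, f1); write_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("models survive a JSON round trip with identical predictions", {
  tiny <- tiny_scenario()
  f <- tempfile(fileext = ".json")
  write_model(tiny$model, f)
  back <- read_model(f)
  for (id in tiny$ds$queries$id[1:5]) {
    a <- predict_de_novo(tiny$ds$profiles[[id]], tiny$model, id = id)
    b <- predict_de_novo(tiny$ds$profiles[[id]], back, id = id)
    expect_equal(b$loc_class, a$loc_class)
    expect_equal(b$ri, a$ri)
    expect_equal(b$path$confidence, a$path$confidence)
  }
})

test_that("de novo predictions reach exactly one leaf with a bounded path", {
  tiny <- tiny_scenario()
  n_internal <- nrow(tiny$model$spec$nodes)
  for (id in tiny$ds$queries$id) {
    p <- predict_de_novo(tiny$ds$profiles[[id]], tiny$model, id = id)
    expect_true(p$loc_class %in% domain_classes("archaea"))
    expect_lte(nrow(p$path), n_internal)
    expect_true(all(p$path$confidence >= 0.5))
    expect_equal(p$ri, round(100 * prod(p$path$confidence)))
    expect_equal(p$source, "DE_NOVO")
    expect_null(p$hit)
  }
})

test_that("the path-product reliability index is anti-monotone", {
  set.seed(13)
  for (i in 1:50) {
    conf <- runif(sample(1:5, 1), 0.5, 1)
    j <- sample(length(conf), 1)
    worse <- conf
    worse[j] <- runif(1, 0.5, conf[j])
    expect_lte(round(100 * prod(worse)), round(100 * prod(conf)))
  }
})

test_that("a single-node two-class tree yields a one-step path", {
  tiny <- tiny_scenario()
  ds <- tiny$ds
  spec2 <- tree_spec("archaea",
                     data.frame(id = "n1", left = "cytosol",
                                right = "plasma membrane"),
                     "n1", classes = c("cytosol", "plasma membrane"))
  keep <- db_class(ds$reference_db, ds$reference$id) %in% spec2$classes
  ids <- ds$reference$id[keep]
  db2 <- annotation_db(ids, db_class(ds$reference_db, ids), "archaea")
  m2 <- train_tree(ds$profiles[ids], db2, spec2, tiny$params)
  p <- predict_de_novo(ds$profiles[[ids[1]]], m2, id = ids[1])
  expect_equal(nrow(p$path), 1L)
  expect_equal(p$ri, round(100 * p$path$confidence[1]))
})
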