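# Accuracy, coverage, Qn, bootstrap standard errors, RI curves.

# small labeled prediction frames built directly
pred_frame <- function(ids, pred, ri = 50L) {
  data.frame(id = ids, loc_class = pred, ri = as.integer(ri),
             expected_accuracy = NA_real_, source = "DE_NOVO",
             stringsAsFactors = FALSE)
}

arc_truth <- function(ids, cls) annotation_db(ids, cls, "archaea")

test_that("confusion counts match direct counting", {
  ids <- paste0("p", 1:10)
  truth <- arc_truth(ids, rep(c("cytosol", "plasma membrane"), each = 5))
  # perfect predictions
  counts <- confusion_counts(pred_frame(ids, db_class(truth, ids)), truth)
  expect_equal(counts$tp, c(5L, 5L))
  expect_equal(counts$fp, c(0L, 0L))
  expect_equal(counts$fn, c(0L, 0L))

  # everything predicted cytosol
  c2 <- confusion_counts(pred_frame(ids, rep("cytosol", 10)), truth)
  cyt <- c2[c2$class == "cytosol", ]
  pm <- c2[c2$class == "plasma membrane", ]
  expect_equal(c(cyt$tp, cyt$fp, cyt$fn), c(5L, 5L, 0L))
  expect_equal(c(pm$tp, pm$fp, pm$fn), c(0L, 0L, 5L))

  expect_error(confusion_counts(pred_frame("zz", "cytosol"), truth),
               "missing")
})

test_that("class merging turns cross-class calls into true positives", {
  truth <- annotation_db("p1", "nucleus", "eukaryota")
  pf <- pred_frame("p1", "nucleus membrane")
  expect_equal(as.numeric(qn(pf, truth)), 0)
  merged <- load_merge_map(system.file("extdata",
                                       "merge_eukaryota_comparison.json",
                                       package = "profloc"))
  expect_equal(as.numeric(qn(pf, truth, merged)), 100)
  counts <- confusion_counts(pf, truth, merged)
  expect_equal(counts$tp[counts$class == "nucleus"], 1L)
})

test_that("merge maps must be total over the domain classes", {
  expect_error(merge_map(c(cytosol = "cytosol"), "archaea"), "not total")
  id <- merge_map(NULL, "archaea")
  expect_equal(unname(unclass(id)), names(id))
})

test_that("accuracy and coverage are exact with NA for empty denominators", {
  counts <- structure(
    data.frame(class = c("a", "b", "c"),
               tp = c(9L, 0L, 0L), fp = c(1L, 0L, 5L),
               fn = c(1L, 10L, 0L), stringsAsFactors = FALSE),
    class = c("eval_counts", "data.frame"))
  expect_equal(class_accuracy(counts, "a"), 90)
  expect_equal(class_coverage(counts, "a"), 90)
  expect_true(is.na(class_accuracy(counts, "b")))   # TP+FP = 0
  expect_equal(class_coverage(counts, "b"), 0)
  expect_equal(class_accuracy(counts, "c"), 0)
  expect_true(is.na(class_coverage(counts, "c")))   # TP+FN = 0
})

test_that("qn is the exact fraction correct and order-invariant", {
  ids <- paste0("p", 1:10)
  cls <- rep(c("cytosol", "plasma membrane"), each = 5)
  truth <- arc_truth(ids, cls)
  pred <- cls
  pred[1:2] <- "extra-cellular"
  pf <- pred_frame(ids, pred)
  expect_equal(as.numeric(qn(pf, truth)), 80)
  expect_equal(as.numeric(qn(pf[sample(10), ], truth)), 80)
  expect_equal(as.numeric(qn(pred_frame(ids, cls), truth)), 100)
  expect_error(qn(pf[0, ], truth), "empty")
})

test_that("merging two cross-predicted classes raises qn from 50 to 100", {
  ids <- paste0("p", 1:4)
  truth <- arc_truth(ids, c("cytosol", "cytosol",
                            "plasma membrane", "plasma membrane"))
  # half the calls land in the sibling class
  pf <- pred_frame(ids, c("cytosol", "plasma membrane",
                          "cytosol", "plasma membrane"))
  expect_equal(as.numeric(qn(pf, truth)), 50)
  mm <- merge_map(c("cytosol" = "inner", "plasma membrane" = "inner",
                    "extra-cellular" = "extra-cellular"), "archaea")
  expect_equal(as.numeric(qn(pf, truth, mm)), 100)
})

test_that("micro consistency: per-class TP sums to the qn numerator", {
  set.seed(31)
  ids <- paste0("p", 1:30)
  classes <- domain_classes("archaea")
  truth <- arc_truth(ids, sample(classes, 30, replace = TRUE))
  pf <- pred_frame(ids, sample(classes, 30, replace = TRUE))
  counts <- confusion_counts(pf, truth)
  q <- qn(pf, truth)
  expect_equal(sum(counts$tp), round(as.numeric(q) * 30 / 100))
})

test_that("bootstrap SE is zero for a constant metric and sigma at n_sets = 2", {
  ids <- paste0("p", 1:20)
  cls <- rep(domain_classes("archaea"), length.out = 20)
  truth <- arc_truth(ids, cls)
  perfect <- pred_frame(ids, cls)
  b <- bootstrap_se(perfect, truth, config = bootstrap_config(50, seed = 3))
  expect_identical(b$sigma, 0)
  expect_identical(b$se, 0)
  expect_equal(b$full, 100)

  pred <- cls
  pred[1:4] <- ifelse(cls[1:4] == "cytosol", "extra-cellular", "cytosol")
  b2 <- bootstrap_se(pred_frame(ids, pred), truth,
                     config = bootstrap_config(2, seed = 3))
  expect_equal(b2$se, b2$sigma)    # divide by sqrt(n - 1) = 1
})

test_that("bootstrap draws follow the documented generator contract", {
  ids <- paste0("p", 1:20)
  cls <- rep(domain_classes("archaea"), length.out = 20)
  truth <- arc_truth(ids, cls)
  pred <- cls
  pred[c(3, 11)] <- ifelse(cls[c(3, 11)] == "cytosol",
                           "plasma membrane", "cytosol")
  pf <- pred_frame(ids, pred)
  cfg <- bootstrap_config(n_sets = 200, fraction = 0.15, seed = 7)
  got <- bootstrap_se(pf, truth, config = cfg)

  # independent brute-force re-implementation of the same contract
  N <- 20L
  m <- as.integer(ceiling(0.15 * N))
  truth_vec <- cls
  correct <- pred == truth_vec
  full <- 100 * mean(correct)
  set.seed(7)
  xs <- replicate(200, {
    idx <- sample.int(N, m)
    100 * mean(correct[idx])
  })
  sigma <- sqrt(sum((xs - full)^2) / 200)
  expect_equal(got$sigma, sigma, tolerance = 1e-12)
  expect_equal(got$se, sigma / sqrt(199), tolerance = 1e-12)
  expect_equal(got$n_skipped, 0L)
})

test_that("bootstrap_se restores the ambient RNG state", {
  ids <- paste0("p", 1:20)
  cls <- rep(domain_classes("archaea"), length.out = 20)
  truth <- arc_truth(ids, cls)
  set.seed(99)
  before <- .Random.seed
  bootstrap_se(pred_frame(ids, cls), truth,
               config = bootstrap_config(10, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("ri_curve starts at full coverage and is non-increasing", {
  set.seed(33)
  ids <- paste0("p", 1:40)
  cls <- sample(domain_classes("archaea"), 40, replace = TRUE)
  truth <- arc_truth(ids, cls)
  pred <- ifelse(runif(40) < 0.8, cls,
                 sample(domain_classes("archaea"), 40, replace = TRUE))
  pf <- pred_frame(ids, pred, ri = sample(0:100, 40, replace = TRUE))
  curve <- ri_curve(pf, truth)
  expect_equal(curve$coverage[1], 100)
  expect_equal(curve$accuracy[1], as.numeric(qn(pf, truth)))
  expect_true(all(diff(curve$coverage) <= 0))
  # direct counting oracle for coverage
  expect_equal(curve$coverage,
               vapply(0:100, function(t) 100 * mean(pf$ri >= t),
                      numeric(1)))
  # threshold above the maximum RI: empty subset
  hi <- ri_curve(pf, truth, thresholds = max(pf$ri) + 1)
  expect_equal(hi$coverage, 0)
  expect_true(is.na(hi$accuracy))
})

test_that("evaluate_predictions assembles a consistent report", {
  tiny <- tiny_scenario()
  ds <- tiny$ds
  preds <- predict_batch(ds$queries, ds$profiles, ds$hits, tiny$model,
                         ds$reference_db)
  rep <- evaluate_predictions(preds, ds$truth,
                              boot = bootstrap_config(50, seed = 2))
  expect_s3_class(rep, "eval_report")
  expect_true(rep$qn >= 0 && rep$qn <= 100)
  expect_equal(rep$n_states, 3L)
  expect_true(all(rep$per_class$acc >= 0 & rep$per_class$acc <= 100,
                  na.rm = TRUE))
  expect_equal(rep$ri_curve$coverage[1], 100)
  expect_output(print(rep), "Q3")
})
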