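## Performance statistics: per-class accuracy (precision) and coverage
## (recall), n-state accuracy Qn, bootstrap standard errors over 15%
## subsamples drawn without replacement, and the reliability-index
## accuracy/coverage curve.

#' Merge map over localization classes
#'
#' A total map class -> merged label, used when comparing across class
#' granularities (e.g. folding membrane classes into their compartment).
#' The identity map leaves every class unchanged.
#'
#' @param map named character vector `class -> merged label` covering
#'   every class of `domain`, or `NULL` for the identity.
#' @inheritParams domain_classes
#' @return Named character vector of class `merge_map`.
#' @export
merge_map <- function(map = NULL, domain) {
  classes <- domain_classes(match_domain(domain))
  if (is.null(map)) map <- stats::setNames(classes, classes)
  missing <- setdiff(classes, names(map))
  if (length(missing))
    stop("merge map is not total; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(map[classes], class = "merge_map")
}

#' Load a merge map from a JSON config
#'
#' Layout: `{"domain": ..., "map": {"class": "merged label", ...}}`.
#'
#' @param path path to the JSON file.
#' @return A `merge_map`.
#' @export
load_merge_map <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  merge_map(unlist(cfg$map), cfg$domain)
}

apply_merge <- function(labels, merge) {
  if (is.null(merge)) return(labels)
  out <- unname(merge[labels])
  if (any(is.na(out) & !is.na(labels)))
    stop("label outside the merge map: ",
         paste(unique(labels[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

as_pred_frame <- function(predictions) {
  if (is.data.frame(predictions)) predictions
  else predictions_frame(predictions)
}

#' Per-class confusion counts
#'
#' For each (merged) class L: TP = predicted and observed in L, FP =
#' predicted in L but observed elsewhere, FN = observed in L but
#' predicted elsewhere. The merge is applied to both predicted and
#' observed labels.
#'
#' @param predictions list of `loc_prediction`s or a data.frame with
#'   `id`, `loc_class`.
#' @param truth an `annotation_db`; every predicted id must be present.
#' @param merge a `merge_map` or `NULL` (identity).
#' @return data.frame of class `eval_counts` with columns `class`, `tp`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, truth, merge = NULL) {
  pf <- as_pred_frame(predictions)
  obs <- db_class(truth, pf$id)
  if (any(is.na(obs)))
    stop("predicted ids missing from the truth set: ",
         paste(head(pf$id[is.na(obs)], 5), collapse = ", "), call. = FALSE)
  pred <- apply_merge(pf$loc_class, merge)
  obs <- apply_merge(obs, merge)
  classes <- sort(unique(c(pred, obs)))
  out <- data.frame(
    class = classes,
    tp = vapply(classes, function(cl) sum(pred == cl & obs == cl),
                integer(1)),
    fp = vapply(classes, function(cl) sum(pred == cl & obs != cl),
                integer(1)),
    fn = vapply(classes, function(cl) sum(pred != cl & obs == cl),
                integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("eval_counts", "data.frame")
  out
}

count_row <- function(counts, cls) {
  r <- counts[counts$class == cls, ]
  if (nrow(r) == 0L) stop("class not present in counts: ", cls,
                          call. = FALSE)
  r
}

#' Per-class accuracy (precision)
#'
#' `100 * TP / (TP + FP)`; `NA` (rendered "n/a" in reports) when the
#' class was never predicted — never 0 or 100.
#'
#' @param counts an `eval_counts` table.
#' @param cls class label.
#' @return Percentage, or `NA_real_` when undefined.
#' @export
class_accuracy <- function(counts, cls) {
  r <- count_row(counts, cls)
  if (r$tp + r$fp == 0L) return(NA_real_)
  100 * r$tp / (r$tp + r$fp)
}

#' Per-class coverage (recall)
#'
#' `100 * TP / (TP + FN)`; `NA` when the class was never observed.
#'
#' @inheritParams class_accuracy
#' @return Percentage, or `NA_real_` when undefined.
#' @export
class_coverage <- function(counts, cls) {
  r <- count_row(counts, cls)
  if (r$tp + r$fn == 0L) return(NA_real_)
  100 * r$tp / (r$tp + r$fn)
}

#' n-state accuracy Qn
#'
#' Percentage of proteins whose (merged) predicted class equals the
#' (merged) observed class. The attribute `n_states` carries the merged
#' class count of the truth labels involved.
#'
#' @inheritParams confusion_counts
#' @return Percentage with attribute `n_states`.
#' @export
qn <- function(predictions, truth, merge = NULL) {
  pf <- as_pred_frame(predictions)
  if (nrow(pf) == 0L) stop("empty evaluation set", call. = FALSE)
  obs <- db_class(truth, pf$id)
  if (any(is.na(obs)))
    stop("predicted ids missing from the truth set", call. = FALSE)
  pred <- apply_merge(pf$loc_class, merge)
  obs <- apply_merge(obs, merge)
  structure(100 * sum(pred == obs) / length(obs),
            n_states = length(unique(obs)))
}

#' Bootstrap configuration
#'
#' The package's bootstrap draws `n_sets` subsamples of
#' `ceiling(fraction * N)` proteins *without replacement* and measures
#' the spread of the metric around its full-set value.
#'
#' @param n_sets number of bootstrap sets, default 1000 (>= 2).
#' @param fraction subsample fraction in (0, 1), default 0.15.
#' @param seed integer seed for the draw sequence.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_sets = 1000, fraction = 0.15, seed = 1) {
  stopifnot(n_sets >= 2, fraction > 0, fraction < 1)
  structure(list(n_sets = as.integer(n_sets), fraction = fraction,
                 replacement = FALSE, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bootstrap standard error of an evaluation metric
#'
#' For each of `n_sets` draws of `ceiling(fraction * N)` proteins without
#' replacement, the metric `x_i` is computed on the subsample. The
#' standard deviation is measured around the *full-set* metric `<x>`
#' (not the bootstrap mean):
#' `sigma = sqrt(sum_i (x_i - <x>)^2 / n)` and
#' `se = sigma / sqrt(n - 1)`, with `n` the number of valid bootstrap
#' sets. A subsample on which the metric is undefined (`NA`) is skipped
#' and counted in `n_skipped`, never imputed.
#'
#' Draw-sequence contract (what a re-implementation must do to
#' reproduce the result): `set.seed(config$seed)` once with R's default
#' Mersenne-Twister generator, then `n_sets` successive calls of
#' `sample.int(N, m)` in row order of the prediction table.
#'
#' @inheritParams confusion_counts
#' @param metric function `(predictions_subset, truth) -> number`;
#'   defaults to [qn()].
#' @param config a [bootstrap_config()].
#' @return List with `se`, `sigma`, `full` (full-set metric), `n_used`,
#'   `n_skipped`.
#' @export
bootstrap_se <- function(predictions, truth, metric = qn,
                         config = bootstrap_config()) {
  pf <- as_pred_frame(predictions)
  N <- nrow(pf)
  m <- as.integer(ceiling(config$fraction * N))
  if (m < 1L) stop("resample size is 0", call. = FALSE)
  full <- as.numeric(metric(pf, truth))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  xs <- vapply(seq_len(config$n_sets), function(i) {
    idx <- sample.int(N, m)
    as.numeric(metric(pf[idx, , drop = FALSE], truth))
  }, numeric(1))
  ok <- !is.na(xs)
  n <- sum(ok)
  if (n < 2L) stop("fewer than 2 valid bootstrap sets", call. = FALSE)
  sigma <- sqrt(sum((xs[ok] - full)^2) / n)
  list(se = sigma / sqrt(n - 1), sigma = sigma, full = full,
       n_used = n, n_skipped = sum(!ok))
}

#' Reliability-index accuracy/coverage curve
#'
#' At each threshold t: coverage is the percentage of predictions with
#' `ri >= t`, accuracy is the Qn of that subset (`NA` when the subset is
#' empty). Coverage is 100% at t = 0 and non-increasing in t.
#'
#' @inheritParams confusion_counts
#' @param thresholds integer grid, default `0:100`.
#' @return data.frame with columns `threshold`, `accuracy`, `coverage`.
#' @export
ri_curve <- function(predictions, truth, thresholds = 0:100,
                     merge = NULL) {
  pf <- as_pred_frame(predictions)
  N <- nrow(pf)
  rows <- lapply(thresholds, function(t) {
    sub <- pf[pf$ri >= t, , drop = FALSE]
    acc <- if (nrow(sub) == 0L) NA_real_
           else as.numeric(qn(sub, truth, merge))
    data.frame(threshold = t, accuracy = acc,
               coverage = 100 * nrow(sub) / N)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Per-class accuracy and coverage, overall Qn with its bootstrap
#' standard error, and the RI curve.
#'
#' @inheritParams confusion_counts
#' @param boot a [bootstrap_config()], or `NULL` to skip the standard
#'   error.
#' @return List of class `eval_report`: `per_class` (data.frame `class`,
#'   `acc`, `cov`), `qn`, `n_states`, `se`, `ri_curve`.
#' @export
evaluate_predictions <- function(predictions, truth, merge = NULL,
                                 boot = bootstrap_config()) {
  pf <- as_pred_frame(predictions)
  counts <- confusion_counts(pf, truth, merge)
  per_class <- data.frame(
    class = counts$class,
    acc = vapply(counts$class, function(cl) class_accuracy(counts, cl),
                 numeric(1)),
    cov = vapply(counts$class, function(cl) class_coverage(counts, cl),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  q <- qn(pf, truth, merge)
  se <- if (is.null(boot)) NA_real_ else
    bootstrap_se(pf, truth,
                 metric = function(p, tr) qn(p, tr, merge),
                 config = boot)$se
  structure(list(per_class = per_class, qn = as.numeric(q),
                 n_states = attr(q, "n_states"), se = se,
                 ri_curve = ri_curve(pf, truth, merge = merge)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> Q%d = %.1f%% +/- %s (bootstrap SE)\n",
              x$n_states, x$qn,
              if (is.na(x$se)) "n/a" else sprintf("%.1f", x$se)))
  pc <- x$per_class
  pc$acc <- ifelse(is.na(pc$acc), "n/a", sprintf("%.1f", pc$acc))
  pc$cov <- ifelse(is.na(pc$cov), "n/a", sprintf("%.1f", pc$cov))
  print(pc, row.names = FALSE)
  invisible(x)
}
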