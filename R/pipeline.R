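## The combiner: homology transfer when a hit survives the filter, the
## de novo SVM tree otherwise; GO-term decoration and expected-accuracy
## lookup from an RI calibration.

#' Load a class -> GO term map
#'
#' Layout: `{"class label": [{"name": ..., "go_id": "GO:NNNNNNN"},
#' ...], ...}`. The shipped default carries one cellular-component term
#' per class and is editable data, not code.
#'
#' @param path JSON file; default the package's shipped map.
#' @return Named list of data.frames (`name`, `go_id`) of class
#'   `go_map`.
#' @export
load_go_map <- function(path = system.file("extdata", "go_map.json",
                                           package = "profloc",
                                           mustWork = TRUE)) {
  tab <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  all_classes <- unique(unlist(lapply(
    c("eukaryota", "bacteria", "archaea"), domain_classes)))
  bad <- setdiff(names(tab), all_classes)
  if (length(bad))
    stop("GO map key is not a known class label: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (cl in names(tab)) {
    ids <- tab[[cl]]$go_id
    if (!all(grepl("^GO:[0-9]{7}$", ids)))
      stop("malformed GO identifier under '", cl, "'", call. = FALSE)
  }
  structure(tab, class = "go_map")
}

#' Attach GO terms to a prediction
#'
#' Sets `go_terms` from the map; an unmapped class gets an empty list.
#' Idempotent.
#'
#' @param pred a `loc_prediction`.
#' @param go_map a `go_map` from [load_go_map()].
#' @return The prediction with `go_terms` set.
#' @export
attach_go <- function(pred, go_map) {
  hit <- go_map[[pred$loc_class]]
  pred$go_terms <- if (is.null(hit)) empty_go() else hit
  pred
}

#' Reliability-index calibration
#'
#' Step-function bins mapping an RI threshold to the accuracy observed
#' on labeled data above that threshold. Produced by [calibrate_ri()],
#' never asserted a priori.
#'
#' @param thresholds strictly increasing integer RI thresholds.
#' @param accuracies observed accuracies (percent) per bin.
#' @inheritParams domain_classes
#' @return Object of class `ri_calibration`.
#' @export
ri_calibration <- function(thresholds, accuracies, domain) {
  stopifnot(length(thresholds) == length(accuracies),
            length(thresholds) >= 1L)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (any(accuracies < 0 | accuracies > 100, na.rm = TRUE))
    stop("accuracies outside [0,100]", call. = FALSE)
  structure(list(domain = match_domain(domain),
                 bins = data.frame(ri_threshold = as.integer(thresholds),
                                   accuracy = as.numeric(accuracies))),
            class = "ri_calibration")
}

#' Build an RI calibration from labeled predictions
#'
#' Evaluates the RI curve on a labeled prediction set and keeps the
#' bins with defined accuracy.
#'
#' @inheritParams confusion_counts
#' @inheritParams domain_classes
#' @param thresholds RI thresholds to bin at, default `seq(0, 90, 10)`.
#' @return An `ri_calibration`.
#' @export
calibrate_ri <- function(predictions, truth, domain,
                         thresholds = seq(0, 90, 10)) {
  curve <- ri_curve(predictions, truth, thresholds)
  keep <- !is.na(curve$accuracy)
  if (!any(keep)) stop("no threshold with defined accuracy", call. = FALSE)
  ri_calibration(curve$threshold[keep], curve$accuracy[keep], domain)
}

#' Expected accuracy for a reliability index
#'
#' Step-function lookup: the accuracy of the highest calibration bin
#' whose threshold is at or below `ri`.
#'
#' @param ri integer reliability index in `[0, 100]`.
#' @param calibration an `ri_calibration`.
#' @return Percentage.
#' @export
expected_accuracy <- function(ri, calibration) {
  stopifnot(ri >= 0, ri <= 100)
  bins <- calibration$bins
  ok <- which(bins$ri_threshold <= ri)
  if (length(ok) == 0L) return(NA_real_)
  bins$accuracy[max(ok)]
}

#' Write / read an RI calibration as JSON
#'
#' @param calibration an `ri_calibration`.
#' @param path file path.
#' @return `path` (write) or an `ri_calibration` (read).
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(list(domain = calibration$domain,
                            bins = calibration$bins),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ri_calibration(obj$bins$ri_threshold, obj$bins$accuracy, obj$domain)
}

#' Combined localization prediction for one query
#'
#' The combination rule: homology-based transfer if any hit survives the
#' filter, the de novo SVM tree otherwise. When no profile is supplied
#' the de novo route fabricates one from the sequence. GO terms are
#' attached for the predicted class and, when a calibration is supplied,
#' the expected accuracy is looked up from the reliability index.
#'
#' @param query one row of a `seq_records` data.frame.
#' @param profile a `seq_profile` or `NULL` (fabricated on demand).
#' @param hits a `blast_hits` table (rows for this query are used) or
#'   `NULL`.
#' @param model a `tree_model` or `NULL`.
#' @param db an `annotation_db` of proteins with known localization (for
#'   the transfer route).
#' @param policy a [transfer_policy()].
#' @param go_map a `go_map` or `NULL`.
#' @param calibration an `ri_calibration` or `NULL`.
#' @return A `loc_prediction`.
#' @export
predict_protein <- function(query, profile = NULL, hits = NULL,
                            model = NULL, db = NULL,
                            policy = transfer_policy(), go_map = NULL,
                            calibration = NULL) {
  homology_ok <- !is.null(hits) && !is.null(db)
  de_novo_ok <- !is.null(model) &&
    (!is.null(profile) || !is.null(query$residues))
  if (!homology_ok && !de_novo_ok)
    stop("no serviceable prediction route (need hits+db or ",
         "profile/sequence+model)", call. = FALSE)
  pred <- NULL
  if (homology_ok)
    pred <- predict_homology(query$id, hits, db, policy)
  if (is.null(pred)) {
    if (!de_novo_ok)
      stop("no surviving hit for '", query$id,
           "' and no de novo model supplied", call. = FALSE)
    if (is.null(profile)) profile <- fabricate_profile(query)
    pred <- predict_de_novo(profile, model, id = query$id)
  }
  if (!is.null(go_map)) pred <- attach_go(pred, go_map)
  if (!is.null(calibration))
    pred$expected_accuracy <- expected_accuracy(pred$ri, calibration)
  pred
}

#' Batch prediction over a record set
#'
#' Streams record by record; a per-query failure is caught, logged via
#' `warning()` and reported in the `failures` attribute rather than
#' aborting the batch. The attribute `homology_fraction` reports the
#' share of predictions made through homology transfer.
#'
#' @param records a `seq_records` data.frame.
#' @param profiles named list of `seq_profile`s (missing entries are
#'   fabricated), or `NULL`.
#' @inheritParams predict_protein
#' @return List of `loc_prediction`s with attributes
#'   `homology_fraction` and `failures` (character ids).
#' @export
predict_batch <- function(records, profiles = NULL, hits = NULL,
                          model = NULL, db = NULL,
                          policy = transfer_policy(), go_map = NULL,
                          calibration = NULL) {
  out <- list()
  failures <- character()
  for (i in seq_len(nrow(records))) {
    q <- records[i, ]
    p <- tryCatch(
      predict_protein(q, profile = profiles[[q$id]], hits = hits,
                      model = model, db = db, policy = policy,
                      go_map = go_map, calibration = calibration),
      error = function(e) {
        warning("prediction failed for '", q$id, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(p)) failures <- c(failures, q$id)
    else out[[q$id]] <- p
  }
  src <- vapply(out, `[[`, character(1), "source")
  attr(out, "homology_fraction") <-
    if (length(out)) unname(mean(src == "HOMOLOGY")) else NA_real_
  attr(out, "failures") <- failures
  out
}
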