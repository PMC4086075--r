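## The per-protein prediction record and its 6-column TSV serialization.

#' Construct a prediction record
#'
#' @param id protein identifier.
#' @param loc_class predicted localization class.
#' @param ri reliability index, integer 0..100.
#' @param source `"HOMOLOGY"` (annotation transfer from the best hit) or
#'   `"DE_NOVO"` (SVM decision tree).
#' @param expected_accuracy expected accuracy in percent, or `NA` when no
#'   reliability calibration is available.
#' @param go_terms data.frame with columns `name`, `go_id`, possibly
#'   empty.
#' @param path for DE_NOVO predictions, data.frame of the decision path
#'   (`node_id`, `side`, `confidence`); must be `NULL` for HOMOLOGY.
#' @param hit for HOMOLOGY predictions, the supporting one-row
#'   `blast_hits` table; must be `NULL` for DE_NOVO.
#' @return Object of class `loc_prediction`.
#' @export
prediction <- function(id, loc_class, ri, source,
                       expected_accuracy = NA_real_,
                       go_terms = empty_go(), path = NULL, hit = NULL) {
  source <- match.arg(source, c("HOMOLOGY", "DE_NOVO"))
  ri <- as.integer(round(ri))
  if (is.na(ri) || ri < 0L || ri > 100L)
    stop("reliability index outside [0,100]", call. = FALSE)
  if (source == "DE_NOVO" && (is.null(path) || nrow(path) == 0L))
    stop("DE_NOVO prediction requires a non-empty decision path",
         call. = FALSE)
  if (source == "DE_NOVO" && !is.null(hit))
    stop("DE_NOVO prediction cannot carry a hit", call. = FALSE)
  if (source == "HOMOLOGY" && is.null(hit))
    stop("HOMOLOGY prediction requires its supporting hit", call. = FALSE)
  if (source == "HOMOLOGY" && !is.null(path))
    stop("HOMOLOGY prediction cannot carry a decision path", call. = FALSE)
  structure(list(id = id, loc_class = loc_class, ri = ri,
                 expected_accuracy = expected_accuracy, source = source,
                 go_terms = go_terms, path = path, hit = hit),
            class = "loc_prediction")
}

empty_go <- function() data.frame(name = character(), go_id = character(),
                                  stringsAsFactors = FALSE)

#' @export
print.loc_prediction <- function(x, ...) {
  cat(sprintf("<prediction> %s -> %s (RI %d, %s)\n", x$id, x$loc_class,
              x$ri, x$source))
  invisible(x)
}

#' Flatten a list of predictions to a data.frame
#'
#' @param predictions list of `loc_prediction` objects.
#' @return data.frame with columns `id`, `loc_class`, `ri`,
#'   `expected_accuracy`, `source`.
#' @export
predictions_frame <- function(predictions) {
  if (inherits(predictions, "loc_prediction"))
    predictions <- list(predictions)
  data.frame(
    id = vapply(predictions, `[[`, character(1), "id"),
    loc_class = vapply(predictions, `[[`, character(1), "loc_class"),
    ri = vapply(predictions, `[[`, integer(1), "ri"),
    expected_accuracy = vapply(predictions, function(p)
      as.numeric(p$expected_accuracy), numeric(1)),
    source = vapply(predictions, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
}

## serialized source tags of the output format
SOURCE_TAGS <- c(HOMOLOGY = "PSI-BLAST", DE_NOVO = "LocTree2")

#' Write predictions to the 6-column TSV report
#'
#' One row per protein with exactly the columns (i) protein identifier,
#' (ii) reliability index, (iii) expected accuracy, (iv) localization
#' class, (v) GO terms as comma-joined `name GO:NNNNNNN` tokens and
#' (vi) source of the prediction (`PSI-BLAST` for homology transfer,
#' `LocTree2` for the de novo tree). Expected accuracy is empty when no
#' calibration was supplied.
#'
#' @param predictions list of `loc_prediction` objects (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  header <- paste(c("id", "ri", "expected_accuracy", "loc_class",
                    "go_terms", "source"), collapse = "\t")
  rows <- vapply(predictions, function(p) {
    go <- if (nrow(p$go_terms)) paste(p$go_terms$name, p$go_terms$go_id,
                                      collapse = ",")
          else ""
    ea <- if (is.na(p$expected_accuracy)) "" else
      format(p$expected_accuracy, trim = TRUE)
    paste(c(p$id, p$ri, ea, p$loc_class, go, SOURCE_TAGS[[p$source]]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a prediction TSV back into a data.frame
#'
#' Inverse of [write_predictions()] at the level of the flat columns
#' (decision paths and supporting hits are not serialized).
#'
#' @param path path to a prediction TSV.
#' @return data.frame with columns `id`, `ri`, `expected_accuracy`,
#'   `loc_class`, `go_terms`, `source` (source mapped back to
#'   `HOMOLOGY`/`DE_NOVO`).
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "character", "character",
                                         "character"))
  if (!identical(names(df), c("id", "ri", "expected_accuracy", "loc_class",
                              "go_terms", "source")))
    stop("not a prediction TSV: ", path, call. = FALSE)
  df$expected_accuracy <- suppressWarnings(as.numeric(df$expected_accuracy))
  rev_map <- stats::setNames(names(SOURCE_TAGS), SOURCE_TAGS)
  df$source <- unname(rev_map[df$source])
  if (any(is.na(df$source))) stop("unknown source tag in ", path,
                                  call. = FALSE)
  df
}
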