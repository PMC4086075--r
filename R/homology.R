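## Homology-based annotation transfer: filter the hit list, take the hit
## with the highest percentage sequence identity, look up its
## experimentally annotated class, and derive the reliability index from
## the identity.

#' Transfer policy for homology-based inference
#'
#' @param evalue_max keep hits with E-value at or below this bound;
#'   default `1e-3`, the standard search gate.
#' @param pide_floor percentage identity at and below which the
#'   reliability index saturates at 0; default 20.
#' @param exclude_self drop hits whose subject equals the query id
#'   (default TRUE).
#' @return Object of class `transfer_policy`.
#' @export
transfer_policy <- function(evalue_max = 1e-3, pide_floor = 20,
                            exclude_self = TRUE) {
  stopifnot(evalue_max > 0, pide_floor >= 0, pide_floor < 100)
  structure(list(evalue_max = evalue_max, pide_floor = pide_floor,
                 exclude_self = exclude_self),
            class = "transfer_policy")
}

#' Filter a hit list for annotation transfer
#'
#' Keeps hits with `evalue <= evalue_max`, removes self-hits (subject id
#' equal to the query id) when the policy says so, and removes hits whose
#' subject has no annotation in `db`. Order is preserved; an empty result
#' is valid. The operation is idempotent.
#'
#' @param hits a `blast_hits` table.
#' @param query_id the query protein id (for self-hit removal).
#' @param policy a [transfer_policy()].
#' @param db an `annotation_db` of proteins with known localization.
#' @return Filtered `blast_hits` table.
#' @export
filter_hits <- function(hits, query_id, policy = transfer_policy(),
                        db = NULL) {
  keep <- hits$evalue <= policy$evalue_max
  if (policy$exclude_self) keep <- keep & hits$subject_id != query_id
  if (!is.null(db)) keep <- keep & hits$subject_id %in% names(db$classes)
  hits[keep, , drop = FALSE]
}

#' Best hit by percentage identity
#'
#' Returns the hit with the highest `pide`; ties are broken by lower
#' E-value, then by input order. Selecting on identity (rather than best
#' E-value) is the transfer rule used throughout the package.
#'
#' @param hits a (filtered) `blast_hits` table.
#' @return A one-row `blast_hits` table, or `NULL` if `hits` is empty.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$pide, hits$evalue, seq_len(nrow(hits)))
  hits[ord[1], , drop = FALSE]
}

#' Reliability index from percentage sequence identity
#'
#' A clamped linear map, 0 at or below the saturation floor
#' (`pide_floor`, default 20) and 100 at full identity:
#' `round(100 * (clamp(pide, floor, 100) - floor) / (100 - floor))`.
#' Monotone non-decreasing in `pide`.
#'
#' @param pide percentage pairwise sequence identity in `[0, 100]`.
#' @param pide_floor saturation floor, default 20.
#' @return Integer reliability index in `[0, 100]`.
#' @export
#' @examples
#' ri_from_pide(c(10, 20, 60, 100))
ri_from_pide <- function(pide, pide_floor = 20) {
  if (any(pide < 0 | pide > 100)) stop("pide outside [0,100]",
                                       call. = FALSE)
  p <- pmin(pmax(pide, pide_floor), 100)
  as.integer(round(100 * (p - pide_floor) / (100 - pide_floor)))
}

#' Homology-based localization prediction
#'
#' Composition of [filter_hits()], [best_hit()] and the class lookup:
#' returns `NULL` when no hit survives filtering, otherwise a
#' `loc_prediction` carrying the annotated class of the best hit's
#' subject, the identity-derived reliability index and the supporting
#' hit.
#'
#' @inheritParams filter_hits
#' @param db an `annotation_db`; the class of the surviving best hit's
#'   subject must be present (a missing class signals a filter/database
#'   inconsistency and is an error).
#' @return A `loc_prediction` with `source = "HOMOLOGY"`, or `NULL`.
#' @export
predict_homology <- function(query_id, hits, db,
                             policy = transfer_policy()) {
  surviving <- filter_hits(hits[hits$query_id == query_id, , drop = FALSE],
                           query_id, policy, db)
  top <- best_hit(surviving)
  if (is.null(top)) return(NULL)
  cls <- db_class(db, top$subject_id)
  if (is.na(cls))
    stop("surviving hit subject '", top$subject_id,
         "' has no annotation (filter/database inconsistency)",
         call. = FALSE)
  prediction(id = query_id, loc_class = cls,
             ri = ri_from_pide(top$pide, policy$pide_floor),
             source = "HOMOLOGY", hit = top)
}
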