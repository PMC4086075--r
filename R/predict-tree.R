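## De novo prediction: walk the SVM tree from root to leaf, multiplying
## per-step confidences into the reliability index.

#' De novo localization prediction for one profile
#'
#' Starting at the root, each node's decision value is computed from the
#' kernel row of the query against the node's support examples; the sign
#' selects the child (a decision value of exactly 0 descends to the
#' positive side), and the Platt sigmoid mapped onto the chosen side
#' (`max(p, 1 - p)`, hence always >= 0.5) is the step confidence. The
#' reliability index is `round(100 * prod(confidences))`, so a path of
#' depth d has an RI floor of `100 * 0.5^d`.
#'
#' @param profile a `seq_profile` of length >= k (or a pre-computed
#'   `kmer_fv`).
#' @param model a `tree_model` from [train_tree()].
#' @param id identifier for the output record; defaults to the profile
#'   id.
#' @return A `loc_prediction` with `source = "DE_NOVO"` and the decision
#'   path (`node_id`, `side`, `confidence`).
#' @export
predict_de_novo <- function(profile, model, id = NULL) {
  if (inherits(profile, "kmer_fv")) {
    fv <- profile
    if (is.null(id)) id <- "query"
  } else {
    if (is.null(id)) id <- profile$id
    fv <- feature_map(profile, model$params)
  }
  krow <- query_krow(fv, model)
  walk_tree(krow, model, id)
}

walk_tree <- function(krow, model, id) {
  spec <- model$spec
  at <- spec$root
  steps <- list()
  while (is_internal(spec, at)) {
    nd <- node_row(spec, at)
    nm <- model$node_models[[at]]
    d <- node_decision(nm, krow)
    side <- if (d >= 0) "right" else "left"
    conf <- node_confidence(nm, d)
    steps[[length(steps) + 1L]] <- data.frame(
      node_id = at, side = side, confidence = conf,
      stringsAsFactors = FALSE)
    at <- if (side == "right") nd$right else nd$left
  }
  path <- do.call(rbind, steps)
  prediction(id = id, loc_class = at,
             ri = round(100 * prod(path$confidence)),
             source = "DE_NOVO", path = path)
}

#' De novo predictions for many profiles at once
#'
#' Equivalent to calling [predict_de_novo()] per profile, but the
#' query-versus-training kernel is computed in one sparse matrix
#' product.
#'
#' @param profiles named list of `seq_profile` objects (or `kmer_fv`s).
#' @param model a `tree_model`.
#' @return Named list of `loc_prediction`s.
#' @export
predict_de_novo_batch <- function(profiles, model) {
  fvs <- profiles_to_fvs(profiles, model$params)
  Kx <- kernel_cross(fvs, model$training_features)
  out <- lapply(seq_along(fvs), function(i)
    walk_tree(Kx[i, ], model, names(fvs)[i]))
  names(out) <- names(fvs)
  out
}
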