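## Training of the hierarchical SVM predictor: one soft-margin SVM per
## internal tree node on the precomputed profile kernel, followed by a
## sigmoid (Platt) calibration of the decision values.

#' Fit the Platt sigmoid on decision values
#'
#' Regularized logistic fit of `P(y = +1 | f) = 1 / (1 + exp(a f + b))`
#' on training decision values, with Laplace-smoothed targets
#' `t+ = (N+ + 1) / (N+ + 2)` and `t- = 1 / (N- + 2)` for small-sample
#' robustness (the classic sigmoid-training scheme). Newton iterations
#' on the cross-entropy objective.
#'
#' @param f numeric decision values.
#' @param y labels in `{-1, +1}`.
#' @return List with `a` (negative for any informative `f`) and `b`.
#' @export
platt_fit <- function(f, y) {
  stopifnot(length(f) == length(y), all(y %in% c(-1, 1)))
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y > 0, hi, lo)
  a <- 0; b <- log((n_neg + 1) / (n_pos + 1))
  obj <- function(a, b) {
    z <- a * f + b
    ## -sum t*log(p) + (1-t)*log(1-p) with p = 1/(1+exp(z)), stable form
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (1 - t) * (-z) + log1p(exp(z))))
  }
  val <- obj(a, b)
  for (iter in 1:100) {
    z <- a * f + b
    p <- 1 / (1 + exp(z))
    ## gradient of the objective w.r.t. (a, b): dF/dz = t - p
    d1 <- t - p
    g <- c(sum(f * d1), sum(d1))
    w <- pmax(p * (1 - p), 1e-12)
    H <- matrix(c(sum(f * f * w), sum(f * w), sum(f * w), sum(w) + 1e-12),
                2, 2)
    step <- tryCatch(solve(H, g), error = function(e) g / max(w))
    ## backtracking line search
    stepsize <- 1
    repeat {
      a2 <- a - stepsize * step[1]; b2 <- b - stepsize * step[2]
      v2 <- obj(a2, b2)
      if (v2 <= val + 1e-9 || stepsize < 1e-10) break
      stepsize <- stepsize / 2
    }
    if (abs(val - v2) < 1e-10 && max(abs(c(a - a2, b - b2))) < 1e-8) {
      a <- a2; b <- b2; break
    }
    a <- a2; b <- b2; val <- v2
  }
  if (a >= 0) {
    ## decision values carry no (or inverted) signal; fall back to a
    ## minimally informative sigmoid so confidences stay near 0.5
    a <- -1e-6; b <- 0
  }
  list(a = a, b = b)
}

#' Train one binary SVM node on a precomputed kernel
#'
#' Solves the soft-margin SVM dual on the kernel matrix (via kernlab's
#' SMO on a `kernelMatrix`), stores the support ids, dual coefficients
#' and bias, normalizes the sign convention so that positive decision
#' values point to the `+1` side, and fits the Platt calibration on the
#' training decision values.
#'
#' @param kmatrix symmetric PSD kernel matrix with unit diagonal and
#'   rownames identifying the training examples.
#' @param labels named vector of `-1`/`+1` labels matching `kmatrix`
#'   rows.
#' @param C soft-margin cost, default 1.
#' @param node_id identifier stored in the model.
#' @return Object of class `node_model` with fields `node_id`,
#'   `support_ids`, `dual_coefs`, `bias`, `platt_a`, `platt_b`.
#' @export
train_node <- function(kmatrix, labels, C = 1, node_id = "node") {
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1/+1",
                                       call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("single-class input at node ", node_id, call. = FALSE)
  if (!all(is.finite(kmatrix))) stop("non-finite kernel entries",
                                     call. = FALSE)
  ids <- rownames(kmatrix)
  y <- as.numeric(labels[ids])
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(kmatrix), y,
                       type = "C-svc", C = C, scaled = FALSE)
  sv <- kernlab::SVindex(fit)
  co <- unlist(kernlab::coef(fit))
  b0 <- kernlab::b(fit)
  dec <- as.numeric(kmatrix[, sv, drop = FALSE] %*% co - b0)
  ## fix the sign convention: positive decision value <=> +1 label side
  if (stats::cor(dec, y) < 0) { co <- -co; b0 <- -b0; dec <- -dec }
  pl <- platt_fit(dec, y)
  structure(list(node_id = node_id, support_ids = ids[sv],
                 dual_coefs = as.numeric(co), bias = b0,
                 platt_a = pl$a, platt_b = pl$b),
            class = "node_model")
}

node_decision <- function(node, krow) {
  ## krow: named kernel values query x training examples (>= supports)
  sum(node$dual_coefs * krow[node$support_ids]) - node$bias
}

node_confidence <- function(node, decision) {
  p <- 1 / (1 + exp(node$platt_a * decision + node$platt_b))
  max(p, 1 - p)
}

#' Train the full hierarchical SVM tree
#'
#' For each internal node of the topology, the training examples are the
#' proteins whose annotated class lies under the node; the binary label
#' is which child subtree holds the class (`left = -1`, `right = +1`).
#' Nodes are trained independently on the shared precomputed kernel.
#'
#' @param profiles named list of `seq_profile` objects (names = protein
#'   ids), or a named list of pre-computed `kmer_fv` feature vectors.
#' @param annotations an `annotation_db` covering all profile ids.
#' @param spec a `tree_spec`; every class must have at least 2 examples.
#' @param params a [kernel_params()] object.
#' @param C soft-margin cost, default 1.
#' @return Object of class `tree_model` with the topology, kernel
#'   parameters, per-node SVMs and the training feature vectors needed
#'   at prediction time.
#' @export
train_tree <- function(profiles, annotations, spec, params, C = 1) {
  fvs <- profiles_to_fvs(profiles, params)
  ids <- names(fvs)
  cls <- db_class(annotations, ids)
  if (any(is.na(cls)))
    stop("unannotated training ids: ",
         paste(head(ids[is.na(cls)], 5), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(cls), spec$classes)
  if (length(bad))
    stop("annotation class outside the tree's class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(cls)
  thin <- names(tab)[tab < 2L]
  if (length(thin))
    stop("classes with fewer than 2 training examples: ",
         paste(thin, collapse = ", "), call. = FALSE)
  K <- kernel_matrix(fvs)
  node_models <- list()
  for (i in seq_len(nrow(spec$nodes))) {
    nd <- spec$nodes[i, ]
    left_cls <- leaves_under(spec, nd$left)
    right_cls <- leaves_under(spec, nd$right)
    in_node <- cls %in% c(left_cls, right_cls)
    lab <- ifelse(cls[in_node] %in% right_cls, 1, -1)
    names(lab) <- ids[in_node]
    node_models[[nd$id]] <- train_node(
      K[ids[in_node], ids[in_node], drop = FALSE], lab, C = C,
      node_id = nd$id)
  }
  structure(list(spec = spec, params = params, C = C,
                 node_models = node_models, training_features = fvs,
                 cache = new.env(parent = emptyenv())),
            class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  cat("<tree_model>", x$spec$domain, "-", length(x$node_models),
      "SVM nodes, k =", x$params$k, ", theta =", x$params$theta,
      ",", length(x$training_features), "training examples\n")
  invisible(x)
}
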