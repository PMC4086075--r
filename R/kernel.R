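## The profile k-mer feature map and normalized string kernel.
##
## A k-mer "hits" a profile position when the sum of the per-position
## residue scores along its k letters is strictly below the threshold
## theta (scores are negative log probabilities, so small = likely). The
## feature vector of a protein counts, over all positions, every hitting
## k-mer; the kernel is the cosine of two such sparse count vectors.

#' Parameters of the profile k-mer kernel
#'
#' @param k k-mer length (>= 1). Domain defaults: 6 for eukaryota, 5 for
#'   bacteria, 3 for archaea (see [default_k()]).
#' @param theta positive score threshold; a k-mer is counted at a
#'   position when its summed profile score is strictly below `theta`.
#'   The default 6.0 admits, on the fabricated-profile scale
#'   (`p_self = 0.9`), the exact k-mer of a window plus its single-
#'   substitution neighbours, keeping feature vectors sparse but
#'   overlapping for related sequences.
#' @param alphabet ordered residue alphabet (default the 20 standard
#'   amino acids).
#' @param allow_large_k permit k > 6 (rejected by default: the
#'   enumeration oracle and the k-mer space become unwieldy).
#' @return Object of class `kernel_params`.
#' @export
kernel_params <- function(k, theta = 6.0, alphabet = aa_alphabet(),
                          allow_large_k = FALSE) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L, length(theta) == 1L)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (k > 6L && !allow_large_k)
    stop("k > 6 rejected by default; set allow_large_k = TRUE",
         call. = FALSE)
  structure(list(k = k, theta = as.numeric(theta),
                 alphabet = as.character(alphabet)),
            class = "kernel_params")
}

#' Score of one k-mer at one profile position
#'
#' Sum over `j = 0..k-1` of `scores[pos + j, kmer[j]]` (0-based `pos`).
#'
#' @param profile a `seq_profile`.
#' @param pos 0-based start position; `pos + k` must not exceed the
#'   profile length.
#' @param kmer residue string of length k.
#' @return A single number.
#' @export
kmer_position_score <- function(profile, pos, kmer) {
  letters_ <- strsplit(kmer, "")[[1]]
  k <- length(letters_)
  if (pos < 0L || pos + k > profile$length)
    stop("position out of range", call. = FALSE)
  idx <- match(letters_, colnames(profile$scores))
  if (any(is.na(idx))) stop("k-mer letter outside the alphabet",
                            call. = FALSE)
  sum(profile$scores[cbind(pos + seq_len(k), idx)])
}

new_kmer_fv <- function(counts, k) {
  counts <- counts[order(names(counts))]
  structure(list(counts = counts, k = as.integer(k),
                 norm = sqrt(sum(as.numeric(counts)^2))),
            class = "kmer_fv")
}

#' @export
print.kmer_fv <- function(x, ...) {
  cat("<kmer_fv> k:", x$k, " distinct k-mers:", length(x$counts),
      " total count:", sum(x$counts), " norm:", round(x$norm, 3), "\n")
  invisible(x)
}

#' Sparse k-mer feature vector of a profile
#'
#' For every position and every k-mer over the alphabet whose
#' [kmer_position_score()] is strictly below `theta`, the k-mer's count
#' is incremented. Implemented as a depth-first trie traversal that
#' prunes any prefix whose partial score already reaches `theta`
#' (children visited in ascending score order, which tightens the
#' pruning; the resulting counts are order-independent).
#'
#' @param profile a `seq_profile` of length >= k.
#' @param params a [kernel_params()] object.
#' @return Object of class `kmer_fv`: sparse named integer counts, `k`
#'   and the Euclidean norm of the count vector.
#' @export
feature_map <- function(profile, params) {
  if (profile$length < params$k)
    stop("profile of length ", profile$length, " is shorter than k = ",
         params$k, call. = FALSE)
  counts <- .feature_map_cpp(profile$scores, params$k, params$theta,
                             params$alphabet)
  new_kmer_fv(counts, params$k)
}

#' Brute-force k-mer feature vector (enumeration oracle)
#'
#' Same contract as [feature_map()], computed by explicitly enumerating
#' all `|alphabet|^k` k-mers at every position. Guarded to
#' `|alphabet|^k <= 1e6`; intended as the independent oracle for the
#' trie implementation and for tiny problems.
#'
#' @inheritParams feature_map
#' @return Object of class `kmer_fv`.
#' @export
brute_force_feature_map <- function(profile, params) {
  k <- params$k
  A <- length(params$alphabet)
  if (A^k > 1e6) stop("alphabet^k exceeds the enumeration guard (1e6)",
                      call. = FALSE)
  if (profile$length < k)
    stop("profile of length ", profile$length, " is shorter than k = ", k,
         call. = FALSE)
  S <- profile$scores
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), k)))  # A^k x k
  kmers <- apply(grid, 1L, function(r)
    paste(params$alphabet[r], collapse = ""))
  total <- integer(length(kmers))
  for (pos in 0:(profile$length - k)) {
    sc <- rowSums(matrix(S[cbind(rep(pos + seq_len(k), each = nrow(grid)),
                                 as.vector(grid))],
                         nrow = nrow(grid)))
    total <- total + (sc < params$theta)
  }
  new_kmer_fv(stats::setNames(total[total > 0L], kmers[total > 0L]), k)
}

#' Normalized kernel between two feature vectors
#'
#' Dot product of the sparse count vectors divided by the product of
#' their Euclidean norms; `kmer_kernel(u, u)` is exactly 1 and values lie
#' in `[0, 1]`.
#'
#' @param u,v `kmer_fv` objects with equal `k`, both non-empty.
#' @return A single number in `[0, 1]`.
#' @export
kmer_kernel <- function(u, v) {
  if (u$k != v$k) stop("mismatched k", call. = FALSE)
  if (length(u$counts) == 0L || length(v$counts) == 0L)
    stop("kernel undefined for an empty feature vector", call. = FALSE)
  common <- intersect(names(u$counts), names(v$counts))
  dot <- sum(as.numeric(u$counts[common]) * as.numeric(v$counts[common]))
  uu <- sum(as.numeric(u$counts)^2)
  vv <- sum(as.numeric(v$counts)^2)
  dot / sqrt(uu * vv)
}

## Sparse feature matrix (distinct k-mers x examples) over a list of
## feature vectors; the workhorse behind kernel_matrix / kernel_cross.
fv_sparse_matrix <- function(fvs, kmer_levels = NULL) {
  nm <- unlist(lapply(fvs, function(f) names(f$counts)),
               use.names = FALSE)
  ## first-occurrence order: deterministic, and row order is irrelevant
  ## to the dot products
  all_kmers <- if (is.null(kmer_levels)) unique(nm) else kmer_levels
  i <- match(nm, all_kmers)  # one hash build over the level set
  j <- rep(seq_along(fvs), vapply(fvs, function(f) length(f$counts),
                                  integer(1)))
  x <- unlist(lapply(fvs, function(f) as.numeric(f$counts)),
              use.names = FALSE)
  keep <- !is.na(i)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(length(all_kmers), length(fvs)),
                       dimnames = list(NULL, names(fvs)))
}

#' Kernel matrix over a list of profiles or feature vectors
#'
#' Entry `(i, j)` is the normalized kernel between the feature vectors of
#' profiles i and j. The matrix is symmetric with unit diagonal and is
#' positive semi-definite up to numerical tolerance.
#'
#' @param profiles list of `seq_profile` objects, or a pre-computed list
#'   of `kmer_fv` objects.
#' @param params a [kernel_params()] object (ignored when feature
#'   vectors are supplied).
#' @return Dense symmetric numeric matrix with dimnames from the list
#'   names.
#' @export
kernel_matrix <- function(profiles, params = NULL) {
  fvs <- profiles_to_fvs(profiles, params)
  X <- fv_sparse_matrix(fvs)
  G <- as.matrix(Matrix::crossprod(X))            # raw integer dot products
  d <- diag(G)
  if (any(d == 0))
    stop("empty feature vector for: ",
         paste(names(fvs)[d == 0], collapse = ", "), call. = FALSE)
  K <- G / sqrt(outer(d, d))                      # exact 1 on the diagonal
  dimnames(K) <- list(names(fvs), names(fvs))
  K
}

#' Cross-kernel between two sets of feature vectors
#'
#' Rectangular matrix of normalized kernel values, rows indexed by
#' `fvs_a`, columns by `fvs_b`.
#'
#' @param fvs_a,fvs_b lists of `kmer_fv` objects (or profiles, with
#'   `params`).
#' @inheritParams kernel_matrix
#' @return Dense numeric matrix `length(fvs_a) x length(fvs_b)`.
#' @export
kernel_cross <- function(fvs_a, fvs_b, params = NULL) {
  fvs_a <- profiles_to_fvs(fvs_a, params)
  fvs_b <- profiles_to_fvs(fvs_b, params)
  kmers <- unique(c(unlist(lapply(fvs_a, function(f) names(f$counts)),
                           use.names = FALSE),
                    unlist(lapply(fvs_b, function(f) names(f$counts)),
                           use.names = FALSE)))
  Xa <- fv_sparse_matrix(fvs_a, kmers)
  Xb <- fv_sparse_matrix(fvs_b, kmers)
  G <- as.matrix(Matrix::crossprod(Xa, Xb))
  na <- vapply(fvs_a, function(f) f$norm, numeric(1))
  nb <- vapply(fvs_b, function(f) f$norm, numeric(1))
  if (any(na == 0) || any(nb == 0))
    stop("empty feature vector in kernel_cross", call. = FALSE)
  K <- G / outer(na, nb)
  dimnames(K) <- list(names(fvs_a), names(fvs_b))
  K
}

## Memoized sparse feature matrix of a model's training examples,
## together with the k-mer level index and per-example norms. Built on
## first use; prediction then reduces to one sparse matrix-vector
## product per query.
training_matrix <- function(model) {
  cache <- model$cache
  if (!exists("X", envir = cache)) {
    fvs <- model$training_features
    levels <- unique(unlist(lapply(fvs, function(f) names(f$counts)),
                            use.names = FALSE))
    assign("levels", levels, envir = cache)
    assign("X", fv_sparse_matrix(fvs, levels), envir = cache)
    assign("norms", vapply(fvs, function(f) f$norm, numeric(1)),
           envir = cache)
  }
  cache
}

## Normalized kernel row of one query feature vector against all
## training examples of a model.
query_krow <- function(fv, model) {
  cache <- training_matrix(model)
  levels <- get("levels", envir = cache)
  idx <- match(names(fv$counts), levels)
  keep <- !is.na(idx)  # query k-mers unseen in training contribute 0
  qv <- Matrix::sparseVector(x = as.numeric(fv$counts)[keep],
                             i = idx[keep], length = length(levels))
  dots <- as.numeric(Matrix::crossprod(get("X", envir = cache), qv))
  krow <- dots / (get("norms", envir = cache) * fv$norm)
  names(krow) <- names(model$training_features)
  krow
}

profiles_to_fvs <- function(x, params) {
  if (length(x) && inherits(x[[1]], "kmer_fv")) return(x)
  if (is.null(params)) stop("params required when passing profiles",
                            call. = FALSE)
  out <- lapply(x, feature_map, params = params)
  if (is.null(names(out)))
    names(out) <- vapply(x, `[[`, character(1), "id")
  out
}
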