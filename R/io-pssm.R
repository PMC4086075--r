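## Per-position residue profiles: the NCBI ASCII PSSM parser and the
## sequence-only fallback profile.
##
## Internal score scale: score = -ln(p) with the per-position residue
## probability p clamped to [0.001, 1]. The clamp bounds every score in
## [0, -ln(0.001) ~= 6.908], which makes the k-mer hit threshold of the
## profile kernel meaningful and the trie traversal prunable.

PROB_FLOOR <- 1e-3

#' Ceiling of the internal profile score scale
#'
#' Profile scores are negative log probabilities, `-ln(p)`, with `p`
#' clamped below at 0.001; the largest possible score is therefore
#' `-ln(0.001)`.
#'
#' @return A single number, about 6.908.
#' @export
score_ceiling <- function() -log(PROB_FLOOR)

new_profile <- function(id, scores, source) {
  stopifnot(is.matrix(scores), ncol(scores) == 20L)
  colnames(scores) <- aa_alphabet()
  if (nrow(scores) == 0L) stop("profile with 0 positions", call. = FALSE)
  if (!all(is.finite(scores))) stop("non-finite profile scores", call. = FALSE)
  if (any(apply(scores, 1L, min) >= score_ceiling()))
    stop("profile row with no score below the clamp ceiling", call. = FALSE)
  structure(list(id = id, length = nrow(scores), scores = scores,
                 source = source),
            class = "seq_profile")
}

#' @export
print.seq_profile <- function(x, ...) {
  cat("<seq_profile> id:", x$id, " length:", x$length,
      " source:", x$source, "\n")
  invisible(x)
}

prob_to_score <- function(p) -log(pmin(pmax(p, PROB_FLOOR), 1))

#' Read an NCBI ASCII position-specific scoring matrix
#'
#' Parses the ASCII PSSM dialect written by PSI-BLAST (`-out_ascii_pssm`):
#' header lines, then one row per sequence position carrying the position
#' index, the query residue, 20 integer log-odds columns and 20
#' percentage columns. The 20 percentage columns (the weighted observed
#' residue frequencies) are converted to the internal negative-log
#' probability scale; the log-odds columns are ignored.
#'
#' @param path path to the PSSM file.
#' @param id identifier for the resulting profile; defaults to the file
#'   name without extension.
#' @return A `seq_profile` with `source = "PARSED_PSSM"`. The attribute
#'   `query_residues` carries the per-position query letters from column 2.
#' @export
read_pssm <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ## data rows start with an integer position index followed by a residue
  is_row <- grepl("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  rows <- lines[is_row]
  if (length(rows) == 0L) stop("no PSSM rows found in '", path, "'",
                               call. = FALSE)
  parsed <- lapply(rows, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 42L)
      stop("truncated PSSM row (", length(tok), " fields): ",
           substr(ln, 1, 60), call. = FALSE)
    pct <- suppressWarnings(as.numeric(tok[23:42]))
    if (any(is.na(pct)))
      stop("non-numeric field in PSSM row: ", substr(ln, 1, 60),
           call. = FALSE)
    list(pos = as.integer(tok[1]), res = toupper(tok[2]), pct = pct)
  })
  pos <- vapply(parsed, `[[`, integer(1), "pos")
  if (!identical(pos, seq_along(pos)))
    stop("PSSM position indices are not consecutive from 1", call. = FALSE)
  ## PSSM column order is the NCBI one (ARNDCQEGHILKMFPSTWYV); reorder to
  ## the package alphabet
  ncbi <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  perm <- match(aa_alphabet(), ncbi)
  scores <- t(vapply(parsed, function(r) prob_to_score(r$pct[perm] / 100),
                     numeric(20)))
  prof <- new_profile(id, scores, "PARSED_PSSM")
  attr(prof, "query_residues") <- paste(
    vapply(parsed, `[[`, character(1), "res"), collapse = "")
  prof
}

#' Fabricate a profile from a bare sequence
#'
#' Deterministic fallback used when no PSSM is available: at each position
#' the observed residue receives probability mass `p_self` and the
#' remaining mass is spread uniformly over the other 19 letters; an `X`
#' position gets a uniform column over all 20 letters. Probabilities are
#' converted to the same negative-log score scale as parsed PSSMs, so the
#' de novo route works identically (if less informedly) without any
#' alignment tooling.
#'
#' @param record one row of a `seq_records` data.frame (or a list with
#'   `id` and `residues`).
#' @param p_self probability mass on the observed residue, default 0.9.
#' @return A `seq_profile` with `source = "FABRICATED"`.
#' @export
#' @examples
#' r <- seq_records("p1", "", "MKVA")
#' fabricate_profile(r[1, ])
fabricate_profile <- function(record, p_self = 0.9) {
  stopifnot(p_self > 0, p_self < 1)
  letters_ <- strsplit(canonicalize_residues(record$residues), "")[[1]]
  alpha <- aa_alphabet()
  scores <- matrix(prob_to_score((1 - p_self) / 19), nrow = length(letters_),
                   ncol = 20L)
  idx <- match(letters_, alpha)
  known <- !is.na(idx)
  scores[cbind(which(known), idx[known])] <- prob_to_score(p_self)
  scores[!known, ] <- prob_to_score(1 / 20)  # X: uniform column
  new_profile(record$id, scores, "FABRICATED")
}

#' Fabricate profiles for a whole record set
#'
#' @param records a `seq_records` data.frame.
#' @inheritParams fabricate_profile
#' @return Named list of `seq_profile` objects, one per record.
#' @export
fabricate_profiles <- function(records, p_self = 0.9) {
  out <- lapply(seq_len(nrow(records)),
                function(i) fabricate_profile(records[i, ], p_self))
  names(out) <- records$id
  out
}
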