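## Tabular BLAST hit lists (outfmt 6, the 12 standard columns).

BLAST6_COLS <- c("query_id", "subject_id", "pide", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' Expects the 12 standard columns `qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`, tab-separated, no
#' header. The percent identity column is stored as `pide`. Hits are
#' returned in file order; an empty file yields an empty hit table.
#'
#' @param path path to the tabular file.
#' @return data.frame of class `blast_hits` with columns
#'   `r paste(BLAST6_COLS, collapse = ", ")`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(blast_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("BLAST tabular line with ", nf[nf != 12L][1],
         " columns (12 expected), line ", which(nf != 12L)[1], call. = FALSE)
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (any(is.na(num)))
    stop("unparseable numeric field in BLAST tabular file, line ",
         which(rowSums(is.na(num)) > 0)[1], call. = FALSE)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2], num,
                   stringsAsFactors = FALSE)
  names(df) <- BLAST6_COLS
  for (cl in c("length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send"))
    df[[cl]] <- as.integer(df[[cl]])
  validate_blast_hits(df)
}

#' Construct an (empty or filled) hit table
#'
#' @param ... columns matching the outfmt-6 layout; omit for an empty
#'   table.
#' @return data.frame of class `blast_hits`.
#' @export
blast_hits <- function(...) {
  args <- list(...)
  if (length(args) == 0L) {
    df <- data.frame(query_id = character(), subject_id = character(),
                     pide = numeric(), length = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric(), bitscore = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(args, stringsAsFactors = FALSE)
    stopifnot(identical(names(df), BLAST6_COLS))
  }
  validate_blast_hits(df)
}

validate_blast_hits <- function(df) {
  if (nrow(df)) {
    if (any(df$pide < 0 | df$pide > 100))
      stop("pide outside [0,100]", call. = FALSE)
    if (any(df$evalue < 0)) stop("negative E-value", call. = FALSE)
    if (any(df$qstart > df$qend | df$sstart > df$send))
      stop("alignment start > end", call. = FALSE)
  }
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Write hits as BLAST tabular (outfmt 6)
#'
#' @param hits a `blast_hits` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- apply(hits, 1L, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(as.character(lines), path)
  invisible(path)
}
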