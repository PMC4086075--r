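## FASTA input/output. Parsing is delegated to Biostrings; this layer adds
## the package's canonicalization and validation contracts.

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order. Residues are uppercased, a terminal
#' `*` is stripped and non-standard letters (B, Z, U, O, J) are mapped to
#' `X`. The record id is the first whitespace-delimited token of the
#' header; the remainder becomes the description. Duplicate ids, empty
#' sequences and letters outside the 21-letter alphabet are errors.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `residues`
#'   (class `seq_records`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records",
                              call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  residues <- canonicalize_residues(as.character(set))
  if (any(nchar(residues) == 0L))
    stop("zero-length sequence for id: ",
         paste(ids[nchar(residues) == 0L], collapse = ", "), call. = FALSE)
  seq_records(ids, desc, residues)
}

#' Construct a set of sequence records
#'
#' @param id,description,residues character vectors of equal length;
#'   `residues` must already be canonical (see [canonicalize_residues()]).
#' @return data.frame of class `seq_records`.
#' @export
seq_records <- function(id, description = "", residues = character()) {
  df <- data.frame(id = as.character(id),
                   description = rep_len(as.character(description), length(id)),
                   residues = as.character(residues),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate record ids", call. = FALSE)
  if (any(nchar(df$residues) == 0L)) stop("empty residue string", call. = FALSE)
  canonicalize_residues(df$residues)  # validates the alphabet
  class(df) <- c("seq_records", "data.frame")
  df
}

#' Write sequence records to FASTA
#'
#' @param records a `seq_records` data.frame (or anything with `id`,
#'   `description`, `residues` columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nchar(records$description) > 0,
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
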