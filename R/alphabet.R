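## Residue alphabet and per-domain localization class sets.

#' The 20 standard amino-acid letters
#'
#' Ordered alphabet used throughout the package: profile matrix columns,
#' k-mer enumeration and sequence validation all follow this order.
#'
#' @return Character vector of 20 single letters.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
}

## letters accepted in input sequences after canonicalization
aa_extended <- function() c(aa_alphabet(), "X")

#' Canonicalize a residue string
#'
#' Uppercases, strips a terminal stop (`*`) and maps the ambiguous or
#' non-standard letters B, Z, U, O and J to `X`. Any remaining character
#' outside the 21-letter alphabet is an error: no position is silently
#' dropped.
#'
#' @param x character vector of residue strings.
#' @return Character vector of the same length.
#' @export
canonicalize_residues <- function(x) {
  x <- toupper(x)
  x <- sub("\\*$", "", x)
  x <- chartr("BZUOJ", "XXXXX", x)
  bad <- !grepl(paste0("^[", paste(aa_extended(), collapse = ""), "]*$"), x)
  if (any(bad)) {
    letters_bad <- unique(unlist(strsplit(gsub(
      paste0("[", paste(aa_extended(), collapse = ""), "]"), "", x[bad]), "")))
    stop("residues outside the amino-acid alphabet after mapping: ",
         paste(letters_bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Localization classes of a domain of life
#'
#' The compartment classes the predictor distinguishes: 18 for eukaryota
#' (10 soluble/non-membrane and 8 membrane classes), 6 for bacteria and 3
#' for archaea.
#'
#' @param domain one of `"eukaryota"`, `"bacteria"`, `"archaea"`.
#' @return Character vector of class labels.
#' @export
#' @examples
#' domain_classes("archaea")
domain_classes <- function(domain = c("eukaryota", "bacteria", "archaea")) {
  domain <- match.arg(domain)
  switch(domain,
    eukaryota = c(
      "chloroplast", "chloroplast membrane",
      "cytosol",
      "endoplasmic reticulum", "endoplasmic reticulum membrane",
      "extra-cellular",
      "golgi apparatus", "golgi apparatus membrane",
      "mitochondrion", "mitochondrion membrane",
      "nucleus", "nucleus membrane",
      "peroxisome", "peroxisome membrane",
      "plasma membrane",
      "plastid",
      "vacuole", "vacuole membrane"),
    bacteria = c("cytosol", "plasma membrane", "periplasmic space",
                 "outer membrane", "fimbrium", "extra-cellular"),
    archaea = c("cytosol", "plasma membrane", "extra-cellular"))
}

match_domain <- function(domain) {
  match.arg(tolower(domain), c("eukaryota", "bacteria", "archaea"))
}

#' Default k-mer length per domain of life
#'
#' The de novo predictor scans profiles with k-consecutive-residue
#' windows; the window length differs by domain: 6 for eukaryota, 5 for
#' bacteria, 3 for archaea.
#'
#' @inheritParams domain_classes
#' @return Integer k.
#' @export
default_k <- function(domain = c("eukaryota", "bacteria", "archaea")) {
  domain <- match.arg(domain)
  c(eukaryota = 6L, bacteria = 5L, archaea = 3L)[[domain]]
}
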