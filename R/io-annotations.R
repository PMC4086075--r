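## Localization annotation tables: one experimentally determined class per
## protein, validated against the class set of a domain of life.

#' Construct an annotation database
#'
#' @param ids character protein identifiers.
#' @param classes character class labels, parallel to `ids`.
#' @param domain domain of life whose class set validates the labels.
#' @return An object of class `annotation_db`: a list with `classes`
#'   (named character vector id -> class) and `domain`.
#' @export
annotation_db <- function(ids, classes, domain) {
  domain <- match_domain(domain)
  ids <- as.character(ids); classes <- as.character(classes)
  stopifnot(length(ids) == length(classes))
  valid <- domain_classes(domain)
  bad <- setdiff(unique(classes), valid)
  if (length(bad))
    stop("class label(s) not in the ", domain, " class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    conflict <- vapply(dup, function(d)
      length(unique(classes[ids == d])) > 1L, logical(1))
    if (any(conflict))
      stop("conflicting annotations (a protein must have a single ",
           "localization): ", paste(dup[conflict], collapse = ", "),
           call. = FALSE)
    keep <- !duplicated(ids)
    ids <- ids[keep]; classes <- classes[keep]
  }
  cls <- classes
  names(cls) <- ids
  structure(list(classes = cls, domain = domain), class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db>", length(x$classes), "proteins,",
      length(unique(x$classes)), "classes, domain:", x$domain, "\n")
  invisible(x)
}

#' @export
length.annotation_db <- function(x) length(x$classes)

#' Look up the annotated class of protein ids
#'
#' @param db an `annotation_db`.
#' @param ids character ids.
#' @return Character vector of class labels (`NA` where unannotated).
#' @export
db_class <- function(db, ids) unname(db$classes[ids])

#' Read an annotation table (TSV: id, class)
#'
#' The file has two tab-separated columns, `id` and `class`, with or
#' without a header line. Labels are validated against the class set of
#' `domain`; a protein listed twice with different classes is an error
#' (each protein carries a single experimental annotation).
#'
#' @param path path to the TSV file.
#' @inheritParams annotation_db
#' @return An `annotation_db`.
#' @export
read_annotations <- function(path, domain) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file: ", path,
                                call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L))
    stop("annotation line without exactly 2 tab-separated columns, line ",
         which(lengths(fields) != 2L)[1], call. = FALSE)
  m <- do.call(rbind, fields)
  if (identical(tolower(m[1, ]), c("id", "class"))) m <- m[-1, , drop = FALSE]
  annotation_db(m[, 1], m[, 2], domain)
}

#' Write an annotation table
#'
#' @param db an `annotation_db`.
#' @param path output path.
#' @param header write an `id<TAB>class` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(db, path, header = TRUE) {
  lines <- paste(names(db$classes), db$classes, sep = "\t")
  if (header) lines <- c("id\tclass", lines)
  writeLines(lines, path)
  invisible(path)
}
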