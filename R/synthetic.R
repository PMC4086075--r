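## Synthetic benchmark generator. Classes are made separable by short
## planted k-mer motifs; homolog pairs are produced at controlled
## percentage identity by point substitution; hit records carry a
## documented monotone E-value proxy so both prediction routes and the
## combiner are exercised without any database search.

#' Scenario configuration for the synthetic generator
#'
#' @param domain domain of life (fixes the class set and default k).
#' @param n_per_class reference (annotated database / training) proteins
#'   per class.
#' @param n_queries_per_class query proteins per class.
#' @param seq_len_range integer `(min, max)` sequence length.
#' @param motifs_per_class distinct planted motifs per class.
#' @param motif_len motif length in residues; must be at least the
#'   domain's default k-mer length.
#' @param motif_insertions_per_seq motif copies planted per sequence.
#' @param background residue sampling frequencies (length 20, need not
#'   be normalized); default uniform -- the generator tests machinery,
#'   not residue composition realism.
#' @param homolog_fraction fraction of queries that are mutated copies
#'   of reference proteins (the WITH_HIT split), in `[0, 1]`.
#' @param target_pide target percentage identity of homolog queries to
#'   their reference, in `(0, 100]`.
#' @param seed integer seed; a fixed seed makes the dataset
#'   byte-reproducible.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(domain = "bacteria", n_per_class = 50,
                            n_queries_per_class = 20,
                            seq_len_range = c(80L, 120L),
                            motifs_per_class = 2, motif_len = 6,
                            motif_insertions_per_seq = 2,
                            background = NULL,
                            homolog_fraction = 0.5, target_pide = 60,
                            seed = 1) {
  domain <- match_domain(domain)
  if (motif_len < default_k(domain))
    stop("motif_len must be >= the domain's k (", default_k(domain), ")",
         call. = FALSE)
  stopifnot(n_per_class >= 1, n_queries_per_class >= 1,
            motifs_per_class >= 1, motif_insertions_per_seq >= 1,
            homolog_fraction >= 0, homolog_fraction <= 1,
            target_pide > 0, target_pide <= 100,
            length(seq_len_range) == 2L,
            seq_len_range[1] <= seq_len_range[2])
  if (seq_len_range[1] < motif_insertions_per_seq * motif_len)
    stop("minimum sequence length too small to host the motif insertions",
         call. = FALSE)
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20L, all(background >= 0),
            sum(background) > 0)
  structure(list(domain = domain, n_per_class = as.integer(n_per_class),
                 n_queries_per_class = as.integer(n_queries_per_class),
                 seq_len_range = as.integer(seq_len_range),
                 motifs_per_class = as.integer(motifs_per_class),
                 motif_len = as.integer(motif_len),
                 motif_insertions_per_seq =
                   as.integer(motif_insertions_per_seq),
                 background = background / sum(background),
                 homolog_fraction = homolog_fraction,
                 target_pide = target_pide, seed = as.integer(seed)),
            class = "scenario_config")
}

with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Class-specific motifs
#'
#' Draws `motifs_per_class` motifs per class, mutually distinct with
#' pairwise Hamming distance >= 2 across the whole set (rejection
#' sampling), so that classes are separable by k-mer content. Seeded
#' from the config; the ambient RNG state is preserved.
#'
#' @param config a [scenario_config()].
#' @return Named list class -> character vector of motifs.
#' @export
make_motifs <- function(config) {
  classes <- domain_classes(config$domain)
  total <- length(classes) * config$motifs_per_class
  if (20^config$motif_len < 10 * total)
    stop("motif space too small for ", total, " distinct motifs",
         call. = FALSE)
  with_preserved_rng({
    set.seed(config$seed)
    draw_motifs(classes, config)
  })
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

draw_motifs <- function(classes, config) {
  alpha <- aa_alphabet()
  accepted <- character()
  tries <- 0L
  total <- length(classes) * config$motifs_per_class
  while (length(accepted) < total) {
    cand <- paste(sample(alpha, config$motif_len, replace = TRUE),
                  collapse = "")
    if (all(vapply(accepted, function(m) hamming(m, cand) >= 2L,
                   logical(1))))
      accepted <- c(accepted, cand)
    tries <- tries + 1L
    if (tries > 1000L * total)
      stop("could not draw motifs at Hamming distance >= 2", call. = FALSE)
  }
  split(accepted, rep(classes, each = config$motifs_per_class))[classes]
}

#' Sample one background sequence with planted class motifs
#'
#' Background residues are drawn from the configured frequency table;
#' `motif_insertions_per_seq` copies of motifs of the class are planted
#' at non-overlapping positions. Draws consume R's global RNG stream
#' (seed it for reproducibility).
#'
#' @param cls class label.
#' @param motifs output of [make_motifs()].
#' @param config a [scenario_config()].
#' @param id record identifier.
#' @return One-row `seq_records` data.frame.
#' @export
sample_sequence <- function(cls, motifs, config, id = "seq") {
  if (!cls %in% names(motifs)) stop("no motifs for class ", cls,
                                    call. = FALSE)
  rng <- config$seq_len_range
  L <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  n_ins <- config$motif_insertions_per_seq
  mlen <- config$motif_len
  if (L < n_ins * mlen)
    stop("sequence length too small to host the insertions", call. = FALSE)
  res <- sample(aa_alphabet(), L, replace = TRUE, prob = config$background)
  ## non-overlapping starts by rejection
  repeat {
    starts <- sort(sample(seq_len(L - mlen + 1L), n_ins))
    if (n_ins == 1L || all(diff(starts) >= mlen)) break
  }
  for (s in starts) {
    m <- motifs[[cls]][sample.int(length(motifs[[cls]]), 1L)]
    res[s:(s + mlen - 1L)] <- strsplit(m, "")[[1]]
  }
  seq_records(id, paste("class:", cls),
              paste(res, collapse = ""))
}

#' Mutate a sequence to a target percentage identity
#'
#' Substitutes `round((1 - target_pide/100) * L)` positions, drawn
#' without replacement, each replaced by a uniformly drawn different
#' letter. Planted motifs enjoy no protection: high-divergence homologs
#' genuinely degrade the de novo signal. Consumes the global RNG
#' stream.
#'
#' @param record one-row `seq_records` data.frame.
#' @param target_pide target identity in `(0, 100]`.
#' @param id identifier for the mutated record.
#' @return List with `record` (the homolog) and `realized_pide`
#'   (`100 * unchanged / L`).
#' @export
make_homolog <- function(record, target_pide, id = paste0(record$id, "_h")) {
  if (target_pide <= 0 || target_pide > 100)
    stop("target_pide must be in (0, 100]", call. = FALSE)
  res <- strsplit(record$residues, "")[[1]]
  L <- length(res)
  n_sub <- round((1 - target_pide / 100) * L)
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      res[p] <- sample(setdiff(aa_alphabet(), res[p]), 1L)
    }
  }
  list(record = seq_records(id, record$description,
                            paste(res, collapse = "")),
       realized_pide = 100 * (L - n_sub) / L)
}

#' Position-wise percentage identity of two residue strings
#'
#' Computed over the overlapping prefix (the generator produces
#' equal-length homologs; decoy comparisons may differ in length).
#'
#' @param a,b residue strings.
#' @return Percentage in `[0, 100]`.
#' @export
pide_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- min(length(x), length(y))
  100 * sum(x[seq_len(n)] == y[seq_len(n)]) / n
}

#' Fabricate a tabular hit record
#'
#' Full-length (over the shorter sequence) hit with `pide` as given and
#' the documented monotone E-value proxy `evalue = 10^(-0.2 * pide)`;
#' this is an explicit surrogate for filterability, not a claim about
#' search statistics. A pide of 60 maps to 1e-12 (passes the default
#' 1e-3 gate); a pide of 0 maps to 1 (fails it).
#'
#' @param query,subject one-row `seq_records` data.frames.
#' @param realized_pide percentage identity to record.
#' @return One-row `blast_hits` table.
#' @export
fabricate_hit <- function(query, subject, realized_pide) {
  stopifnot(realized_pide >= 0, realized_pide <= 100)
  len <- min(nchar(query$residues), nchar(subject$residues))
  blast_hits(query_id = query$id, subject_id = subject$id,
             pide = realized_pide, length = len,
             mismatch = as.integer(round((1 - realized_pide / 100) * len)),
             gapopen = 0L,
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = 10^(-0.2 * realized_pide),
             bitscore = round(2 * len * realized_pide / 100, 1))
}

#' Generate a full synthetic dataset
#'
#' Builds an annotated reference set (`n_per_class` proteins per class)
#' and a query set. A `homolog_fraction` of the queries per class are
#' mutated copies of distinct reference proteins at `target_pide`
#' identity (split `WITH_HIT`, fabricated hit included); the remainder
#' are fresh draws from the class (split `WITHOUT_HIT`) that carry a
#' decoy hit against a random reference at background identity, whose
#' proxy E-value fails the default transfer gate (decoy subjects are
#' redrawn in the rare case background identity would pass it, so the
#' split is exactly recoverable from the hits plus the default policy).
#' Profiles are fabricated for every record.
#'
#' @param config a [scenario_config()].
#' @return Object of class `synthetic_dataset`: `queries`, `reference`
#'   (both `seq_records`), `profiles` (named list over all ids),
#'   `truth` (annotation_db over all records), `reference_db`
#'   (annotation_db over the reference ids only), `hits`, `split`
#'   (named `WITH_HIT`/`WITHOUT_HIT`), `reference_db_ids`, `motifs`,
#'   `config`.
#' @export
make_dataset <- function(config) {
  classes <- domain_classes(config$domain)
  motifs <- make_motifs(config)
  with_preserved_rng({
    set.seed(config$seed)
    ref_rows <- list(); qry_rows <- list()
    hit_rows <- list(); split <- character()
    ref_class <- character(); qry_class <- character()
    for (ci in seq_along(classes)) {
      cls <- classes[ci]
      for (j in seq_len(config$n_per_class)) {
        id <- sprintf("ref_c%02d_%03d", ci, j)
        ref_rows[[id]] <- sample_sequence(cls, motifs, config, id)
        ref_class[id] <- cls
      }
      n_q <- config$n_queries_per_class
      n_hom <- round(config$homolog_fraction * n_q)
      src <- if (n_hom > 0L)
        sample.int(config$n_per_class, n_hom,
                   replace = n_hom > config$n_per_class)
      else integer()
      for (j in seq_len(n_q)) {
        id <- sprintf("qry_c%02d_%03d", ci, j)
        if (j <= n_hom) {
          parent <- ref_rows[[sprintf("ref_c%02d_%03d", ci, src[j])]]
          hm <- make_homolog(parent, config$target_pide, id)
          qry_rows[[id]] <- hm$record
          hit_rows[[id]] <- fabricate_hit(hm$record, parent,
                                          hm$realized_pide)
          split[id] <- "WITH_HIT"
        } else {
          qry_rows[[id]] <- sample_sequence(cls, motifs, config, id)
          split[id] <- "WITHOUT_HIT"
        }
        qry_class[id] <- cls
      }
    }
    reference <- do.call(rbind, ref_rows)
    class(reference) <- c("seq_records", "data.frame")
    queries <- do.call(rbind, qry_rows)
    class(queries) <- c("seq_records", "data.frame")
    ## decoy hits for the WITHOUT_HIT split: background identity against
    ## a random reference; redraw if the proxy E-value would pass the
    ## default gate (guarantees exact split recoverability)
    for (id in names(split)[split == "WITHOUT_HIT"]) {
      repeat {
        subj <- reference[sample.int(nrow(reference), 1L), ]
        p <- pide_identity(qry_rows[[id]]$residues, subj$residues)
        if (10^(-0.2 * p) > transfer_policy()$evalue_max) break
      }
      hit_rows[[id]] <- fabricate_hit(qry_rows[[id]], subj, p)
    }
    hits <- do.call(rbind, hit_rows[queries$id])
    class(hits) <- c("blast_hits", "data.frame")
    truth <- annotation_db(c(names(ref_class), names(qry_class)),
                           c(ref_class, qry_class), config$domain)
    reference_db <- annotation_db(names(ref_class), ref_class,
                                  config$domain)
    profiles <- fabricate_profiles(rbind(reference, queries))
    structure(list(queries = queries, reference = reference,
                   profiles = profiles, truth = truth,
                   reference_db = reference_db, hits = hits,
                   split = split,
                   reference_db_ids = reference$id,
                   motifs = motifs, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", x$config$domain, "-",
      nrow(x$reference), "reference +", nrow(x$queries), "queries (",
      sum(x$split == "WITH_HIT"), "WITH_HIT /",
      sum(x$split == "WITHOUT_HIT"), "WITHOUT_HIT )\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `queries.fasta`, `reference.fasta`, `truth.tsv`,
#' `reference_annotations.tsv`, `hits.tsv` and `scenario.json` (full
#' config incl. seed, for provenance).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$queries, file.path(dir, "queries.fasta"))
  write_fasta(ds$reference, file.path(dir, "reference.fasta"))
  write_annotations(ds$truth, file.path(dir, "truth.tsv"))
  write_annotations(ds$reference_db,
                    file.path(dir, "reference_annotations.tsv"))
  write_blast_tab(ds$hits, file.path(dir, "hits.tsv"))
  cfg <- unclass(ds$config)
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
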