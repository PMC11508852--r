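.RANKS <- c("d", "p", "c", "o", "f", "g", "s")

.validate_lineage <- function(lin) {
  if (length(lin) == 0L || is.null(names(lin)) || any(!nzchar(lin))) {
    stop("reference_db: lineages must be non-empty named rank vectors")
  }
  pos <- match(names(lin), .RANKS)
  if (anyNA(pos) || is.unsorted(pos, strictly = TRUE)) {
    stop("reference_db: lineage ranks must be drawn from d,p,c,o,f,g,s in order")
  }
  invisible(lin)
}

#' Taxonomy-annotated reference database
#'
#' Holds reference sequences with ordered rank lineages (single-letter ranks
#' `d,p,c,o,f,g,s`; intermediate ranks may be missing) whose species rank,
#' where present, carries a UNITE-style species-hypothesis (SH) code. A
#' shared k-mer index for classification is built lazily by
#' [build_kmer_index].
#'
#' @param accession Character vector of record identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @param lineage List of named character vectors (names = ranks).
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(accession, seq, lineage) {
  n <- length(accession)
  stopifnot(length(seq) == n, length(lineage) == n)
  if (anyDuplicated(accession)) stop("reference_db: duplicate accessions")
  lapply(lineage, .validate_lineage)
  structure(list(accession = as.character(accession),
                 seq = toupper(as.character(seq)),
                 lineage = lineage, index = NULL),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d reference(s), %d with an SH code\n",
              length(x$accession),
              sum(vapply(x$lineage, function(l) "s" %in% names(l), logical(1)))))
  invisible(x)
}

.format_sintax_header <- function(accession, lineage) {
  paste0(">", accession, ";tax=",
         paste(paste0(names(lineage), ":", lineage), collapse = ","), ";")
}

#' Read and write SINTAX-formatted reference FASTA
#'
#' The header grammar is
#' `>ID;tax=d:...,p:...,...,s:SHxxxxxxx.10FU;` — single-letter rank
#' prefixes, commas between ranks, missing intermediate ranks permitted, a
#' trailing semicolon tolerated. A header without `tax=` raises an error
#' naming the record.
#'
#' @param path FASTA path.
#' @param db A [reference_db].
#' @return `load_sintax_db()` returns a [reference_db]; `write_sintax_db()`
#'   returns `path` invisibly.
#' @export
load_sintax_db <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop(sprintf("load_sintax_db: no records in '%s'", path))
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  acc <- character(length(hdr_idx))
  lineage <- vector("list", length(hdr_idx))
  seqs <- character(length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    hdr <- sub("^>", "", lines[hdr_idx[i]])
    if (!grepl(";tax=", hdr, fixed = TRUE)) {
      stop(sprintf("load_sintax_db: record '%s' lacks a ';tax=' annotation",
                   sub(";.*$", "", hdr)))
    }
    parts <- strsplit(hdr, ";tax=", fixed = TRUE)[[1L]]
    acc[i] <- parts[1L]
    tax <- sub(";\\s*$", "", parts[2L])
    if (!nzchar(tax)) {
      stop(sprintf("load_sintax_db: record '%s' has an empty taxonomy", acc[i]))
    }
    fields <- strsplit(tax, ",", fixed = TRUE)[[1L]]
    rk <- sub(":.*$", "", fields)
    nm <- sub("^[a-z]:", "", fields)
    lin <- stats::setNames(nm, rk)
    lineage[[i]] <- lin
    body <- lines[(hdr_idx[i] + 1L):ends[i]]
    seqs[i] <- toupper(paste(body, collapse = ""))
  }
  reference_db(acc, seqs, lineage)
}

#' @rdname load_sintax_db
#' @export
write_sintax_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  out <- character(2L * length(db$accession))
  out[c(TRUE, FALSE)] <- mapply(.format_sintax_header, db$accession,
                                db$lineage, USE.NAMES = FALSE)
  out[c(FALSE, TRUE)] <- db$seq
  writeLines(out, path)
  invisible(path)
}

#' Add a reference with a dummy SH code
#'
#' Appends a sequence whose species rank carries an unused dummy SH code
#' matching `SH\\d{7}\\.10FU`; the k-mer index is invalidated so the new
#' record is immediately queryable.
#'
#' @param db A [reference_db].
#' @param seq Nucleotide sequence to add.
#' @param lineage Named rank vector ending in the dummy SH at rank `s`.
#' @param accession Record id; defaults to the SH code.
#' @return The extended [reference_db].
#' @export
add_reference <- function(db, seq, lineage, accession = NULL) {
  stopifnot(inherits(db, "reference_db"))
  .validate_lineage(lineage)
  sh <- lineage[["s"]]
  if (is.null(sh) || !grepl("^SH[0-9]{7}\\.10FU$", sh)) {
    stop("add_reference: lineage must end in an SH code matching SH\\d{7}.10FU")
  }
  existing <- unlist(lapply(db$lineage, function(l) l["s"]), use.names = FALSE)
  if (sh %in% existing) {
    stop(sprintf("add_reference: SH code '%s' already present", sh))
  }
  if (is.null(accession)) accession <- sh
  db$accession <- c(db$accession, accession)
  db$seq <- c(db$seq, toupper(seq))
  db$lineage <- c(db$lineage, list(lineage))
  db$index <- NULL
  db
}

#' SINTAX-style classification parameters
#'
#' Defaults follow the published k-mer bootstrap classifier: 8-mers, 32
#' k-mers per bootstrap, 100 bootstraps. The dual confidence thresholds are
#' the classifiability filter: singleton zOTUs must reach species confidence
#' 0.95, multiton zOTUs 0.8.
#'
#' @param k K-mer size.
#' @param n_boot Number of bootstrap draws.
#' @param n_kmers K-mers sampled (with replacement) per bootstrap.
#' @param singleton_cutoff,multiton_cutoff Species-rank confidence cutoffs
#'   in \[0, 1\], `singleton_cutoff >= multiton_cutoff`.
#' @param seed Integer seed for bootstrap sampling and tie-breaks.
#' @return An object of class `classify_params`.
#' @export
classify_params <- function(k = 8L, n_boot = 100L, n_kmers = 32L,
                            singleton_cutoff = 0.95, multiton_cutoff = 0.8,
                            seed = 1L) {
  stopifnot(k >= 3L, n_boot >= 1L, n_kmers >= 1L,
            singleton_cutoff >= 0, singleton_cutoff <= 1,
            multiton_cutoff >= 0, multiton_cutoff <= 1,
            singleton_cutoff >= multiton_cutoff)
  structure(list(k = as.integer(k), n_boot = as.integer(n_boot),
                 n_kmers = as.integer(n_kmers),
                 singleton_cutoff = singleton_cutoff,
                 multiton_cutoff = multiton_cutoff,
                 seed = as.integer(seed)),
            class = "classify_params")
}

#' Build (or rebuild) the reference k-mer index
#'
#' @param db A [reference_db].
#' @param k K-mer size.
#' @return The [reference_db] with its index populated.
#' @export
build_kmer_index <- function(db, k = 8L) {
  per_ref <- lapply(db$seq, .kmers, k = k)
  dict <- unique(unlist(per_ref, use.names = FALSE))
  M <- matrix(FALSE, nrow = length(dict), ncol = length(db$seq))
  for (j in seq_along(per_ref)) {
    M[match(per_ref[[j]], dict), j] <- TRUE
  }
  storage.mode(M) <- "integer"
  db$index <- list(k = as.integer(k), dict = dict, M = M)
  db
}

# one classification under the current RNG stream
.sintax_one <- function(query, db, params) {
  if (nchar(query) < params$k) {
    stop("sintax_classify: query shorter than the k-mer size")
  }
  idx <- db$index
  qk <- .kmers_all(query, idx$k)
  ids <- match(qk, idx$dict)
  nref <- ncol(idx$M)
  Mq <- matrix(0L, nrow = length(qk), ncol = nref)
  hitrows <- !is.na(ids)
  Mq[hitrows, ] <- idx$M[ids[hitrows], , drop = FALSE]
  draw <- sample.int(length(qk), params$n_kmers * params$n_boot,
                     replace = TRUE)
  S <- rowsum(Mq[draw, , drop = FALSE],
              group = rep(seq_len(params$n_boot), each = params$n_kmers))
  top <- max.col(S, ties.method = "random")
  top_score <- S[cbind(seq_len(params$n_boot), top)]
  conf <- stats::setNames(numeric(length(.RANKS)), .RANKS)
  pred <- stats::setNames(rep(NA_character_, length(.RANKS)), .RANKS)
  for (r in .RANKS) {
    vals <- vapply(db$lineage[top], function(l) {
      v <- l[r]
      if (is.na(v)) NA_character_ else unname(v)
    }, character(1))
    tab <- table(vals[!is.na(vals)])
    if (length(tab) > 0L) {
      w <- which.max(tab)
      pred[r] <- names(tab)[w]
      conf[r] <- as.numeric(tab[w]) / params$n_boot
    }
  }
  modal_top <- names(sort(table(db$accession[top]), decreasing = TRUE))[1L]
  structure(list(ranks = pred, confidence = conf, top_hit = modal_top,
                 unclassifiable = all(top_score == 0L)),
            class = "sintax_classification")
}

#' K-mer bootstrap taxonomy classification of a single query
#'
#' For each bootstrap, `n_kmers` query k-mers are drawn with replacement and
#' the reference sharing most of them is the bootstrap's top hit (ties
#' broken by a seeded uniform draw). Per-rank confidence is the fraction of
#' bootstraps whose top hit carries that rank value; the prediction is the
#' modal value per rank. Confidences are non-increasing from domain to
#' species by construction.
#'
#' @param query Nucleotide string, at least `k` bases.
#' @param db A [reference_db] (indexed automatically if needed).
#' @param params A [classify_params].
#' @return An object of class `sintax_classification`: named `ranks`
#'   (predictions), `confidence`, `top_hit`, and an `unclassifiable` flag
#'   set when no bootstrap shared a single k-mer with any reference.
#' @export
sintax_classify <- function(query, db, params = classify_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (is.null(db$index) || db$index$k != params$k) {
    db <- build_kmer_index(db, params$k)
  }
  .with_seed(params$seed, .sintax_one(query, db, params))
}

#' @export
print.sintax_classification <- function(x, ...) {
  shown <- !is.na(x$ranks)
  cat("<sintax_classification>",
      paste(sprintf("%s:%s(%.2f)", names(x$ranks)[shown], x$ranks[shown],
                    x$confidence[shown]), collapse = ","), "\n")
  invisible(x)
}

#' Classify a set of sequences
#'
#' Batch interface over [sintax_classify]: the seed is applied once, so a
#' fixed seed and input order give identical confidences.
#'
#' @param seqs Character vector of query sequences.
#' @param db A [reference_db].
#' @param params A [classify_params].
#' @return data.frame with one row per query: `species` (the species-rank
#'   prediction, an SH code for SH-annotated references), `conf_species`,
#'   one `conf_<rank>` column per rank, `top_hit` and `unclassifiable`.
#' @export
classify_zotus <- function(seqs, db, params = classify_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (is.null(db$index) || db$index$k != params$k) {
    db <- build_kmer_index(db, params$k)
  }
  res <- .with_seed(params$seed,
                    lapply(seqs, .sintax_one, db = db, params = params))
  out <- data.frame(
    species = vapply(res, function(r) r$ranks[["s"]], character(1)),
    conf_species = vapply(res, function(r) r$confidence[["s"]], numeric(1)),
    top_hit = vapply(res, function(r) r$top_hit, character(1)),
    unclassifiable = vapply(res, function(r) r$unclassifiable, logical(1)),
    stringsAsFactors = FALSE
  )
  for (r in .RANKS) {
    out[[paste0("name_", r)]] <-
      vapply(res, function(x) x$ranks[[r]], character(1))
    out[[paste0("conf_", r)]] <-
      vapply(res, function(x) x$confidence[[r]], numeric(1))
  }
  out
}

#' Dual-threshold classifiability filter
#'
#' A zOTU is kept when its species-rank confidence reaches the singleton
#' cutoff (default 0.95) if it is supported by a single read, or the relaxed
#' multiton cutoff (default 0.8) if supported by two or more reads —
#' multi-read zOTUs are less likely to be driven by sequencing error.
#'
#' @param size Integer vector of zOTU read counts.
#' @param species_conf Numeric vector of species-rank confidences.
#' @param params A [classify_params].
#' @return Logical keep vector.
#' @export
apply_confidence_filter <- function(size, species_conf,
                                    params = classify_params()) {
  stopifnot(length(size) == length(species_conf))
  conf <- ifelse(is.na(species_conf), -Inf, species_conf)
  (size == 1L & conf >= params$singleton_cutoff) |
    (size >= 2L & conf >= params$multiton_cutoff)
}

#' Aggregate conspecific zOTUs into an SH table
#'
#' Per-sample counts of zOTUs sharing a species hypothesis are summed; row
#' labels of the result are SH codes and totals equal the retained zOTU
#' totals.
#'
#' @param table A zOTU [unit_table] (rows = retained zOTUs).
#' @param sh Character vector of SH codes, one per row of `table`.
#' @return An SH [unit_table].
#' @export
aggregate_sh <- function(table, sh) {
  stopifnot(inherits(table, "unit_table"))
  if (nrow(table) == 0L) {
    return(unit_table(table[0, , drop = FALSE], kind = "SH"))
  }
  if (length(sh) != nrow(table) || anyNA(sh) || any(!nzchar(sh))) {
    stop("aggregate_sh: every retained zOTU must carry an SH code")
  }
  m <- rowsum(unclass(table), group = sh)
  unit_table(m[order(rownames(m)), , drop = FALSE], kind = "SH")
}

#' Read-weighted classification rate
#'
#' The fraction of reads whose zOTU passes the dual-threshold
#' classifiability filter, weighted by zOTU read count.
#'
#' @param zotus A `zotu_set` from [dereplicate].
#' @param db A [reference_db].
#' @param params A [classify_params].
#' @return Fraction in \[0, 1\].
#' @export
classification_rate <- function(zotus, db, params = classify_params()) {
  stopifnot(inherits(zotus, "zotu_set"))
  if (length(zotus$size) == 0L) {
    stop("classification_rate: empty zOTU set")
  }
  cls <- classify_zotus(zotus$seq, db, params)
  keep <- apply_confidence_filter(zotus$size, cls$conf_species, params)
  sum(zotus$size[keep]) / sum(zotus$size)
}
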