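#' Taxonomic-unit count table
#'
#' An integer matrix of units (rows: zOTUs, OTUs or SHs) by samples
#' (columns), tagged with its unit kind. All-zero rows are removed at
#' construction; column sums equal the retained reads per sample.
#'
#' @param counts Non-negative integer matrix with row and column names.
#' @param kind One of `"zOTU"`, `"OTU"`, `"SH"`.
#' @return An object of class `unit_table` (a classed matrix).
#' @export
unit_table <- function(counts, kind = c("zOTU", "OTU", "SH")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("unit_table: counts need column names")
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("unit_table: counts must be non-negative integers")
  }
  if (nrow(counts) > 0L) {
    counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  }
  structure(counts, class = c("unit_table", class(counts)), kind = kind)
}

#' @export
print.unit_table <- function(x, ...) {
  cat(sprintf("<unit_table:%s> %d unit(s) x %d sample(s), %d read(s)\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(x)))
  if (nrow(x) > 0L) {
    utils::head(as.data.frame(unclass(x)), 10L) |> print()
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Write / read a unit table as TSV (units as rows, samples as columns)
#'
#' @param table A [unit_table].
#' @param path File path.
#' @param kind Unit kind tag applied when reading.
#' @return The table (reading) or `path` invisibly (writing).
#' @export
write_unit_table <- function(table, path) {
  df <- data.frame(unit = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_unit_table
#' @export
read_unit_table <- function(path, kind = "OTU") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$unit
  unit_table(m, kind = kind)
}

#' Dereplicate reads into zero-radius OTUs
#'
#' One zOTU per distinct sequence string, with per-sample counts preserved.
#' zOTUs are ordered by decreasing total size, ties broken lexicographically
#' by sequence.
#'
#' @param reads A [quality_reads] object (trimmed and oriented).
#' @return An object of class `zotu_set`: parallel `label`, `seq`, `size`
#'   vectors and a zOTU [unit_table] in the same row order.
#' @export
dereplicate <- function(reads) {
  stopifnot(inherits(reads, "quality_reads"))
  samples <- sort(unique(reads$sample))
  if (length(samples) == 0L) samples <- "s1"
  uniq <- unique(reads$seq)
  cnt <- table(factor(reads$seq, levels = uniq),
               factor(reads$sample, levels = samples))
  m <- matrix(as.integer(cnt), nrow = length(uniq),
              dimnames = list(NULL, samples))
  size <- rowSums(m)
  ord <- order(-size, uniq)
  m <- m[ord, , drop = FALSE]
  labels <- sprintf("Z%05d", seq_along(uniq))
  rownames(m) <- labels
  structure(list(label = labels, seq = uniq[ord],
                 size = as.integer(size[ord]),
                 table = unit_table(m, kind = "zOTU")),
            class = "zotu_set")
}

#' @export
print.zotu_set <- function(x, ...) {
  cat(sprintf("<zotu_set> %d zOTU(s), %d read(s), %d singleton(s)\n",
              length(x$size), sum(x$size), sum(x$size == 1L)))
  invisible(x)
}

#' Subset a zOTU set
#'
#' @param zotus A `zotu_set`.
#' @param keep Logical or integer index over zOTUs.
#' @return The subsetted `zotu_set`.
#' @export
zotu_subset <- function(zotus, keep) {
  stopifnot(inherits(zotus, "zotu_set"))
  m <- unclass(zotus$table)[keep, , drop = FALSE]
  structure(list(label = zotus$label[keep], seq = zotus$seq[keep],
                 size = zotus$size[keep],
                 table = unit_table(m, kind = "zOTU")),
            class = "zotu_set")
}

#' Greedy clustering parameters
#'
#' @param identity_t Identity threshold in (0.5, 1\]; the clustering radius
#'   is `1 - identity_t` (default 0.02, i.e. 98% OTUs).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(identity_t = 0.98) {
  stopifnot(identity_t > 0.5, identity_t <= 1)
  structure(list(identity_t = identity_t, radius = 1 - identity_t),
            class = "cluster_params")
}

# conservative edit budget for a pair to possibly reach identity >= t
.max_diffs_for <- function(t, la, lb) {
  as.integer(ceiling((1 - t) * (max(la, lb) + 10)) + 2L)
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' zOTUs are processed in decreasing size order. Each is assigned to the
#' best-matching existing centroid whose pairwise identity reaches
#' `identity_t` (ties broken by larger centroid founding size, then
#' lexicographically); otherwise it founds a new centroid. A conservative
#' shared-k-mer screen skips centroid/query pairs that cannot reach the
#' threshold, so best-match semantics are preserved. OTU abundances are the
#' per-sample sums of their member zOTUs.
#'
#' @param zotus A `zotu_set` (size-sorted, as produced by [dereplicate]).
#' @param params A [cluster_params].
#' @return List with `table` (OTU [unit_table]), `centroids` (named
#'   character vector, OTU label -> centroid sequence) and `membership`
#'   (named character vector, zOTU label -> OTU label).
#' @export
greedy_cluster <- function(zotus, params = cluster_params()) {
  stopifnot(inherits(zotus, "zotu_set"), inherits(params, "cluster_params"))
  n <- length(zotus$seq)
  t <- params$identity_t
  k <- 8L
  kindex <- new.env(parent = emptyenv(), hash = TRUE)
  cent_seq <- character(0)
  cent_len <- integer(0)
  cent_founder_size <- integer(0)
  assign_to <- integer(n)
  for (i in seq_len(n)) {
    q <- zotus$seq[i]
    lq <- nchar(q)
    qk <- .kmers(q, k)
    best <- 0L
    if (length(cent_seq) > 0L && length(qk) > 0L) {
      hits <- unlist(mget(qk, envir = kindex, ifnotfound = list(integer(0))),
                     use.names = FALSE)
      shared <- tabulate(hits, nbins = length(cent_seq))
      dmax <- .max_diffs_for(t, lq, cent_len)
      cand <- which(shared >= length(qk) - k * dmax)
      if (length(cand) > 0L) {
        ident <- vapply(cand, function(j) {
          .identity_banded(q, cent_seq[j], .max_diffs_for(t, lq, cent_len[j]))
        }, numeric(1))
        ok <- ident >= t
        if (any(ok)) {
          cand <- cand[ok]
          ident <- ident[ok]
          top <- ident == max(ident)
          pick <- cand[top]
          if (length(pick) > 1L) {
            pick <- pick[order(-cent_founder_size[pick], cent_seq[pick])]
          }
          best <- pick[1L]
        }
      }
    }
    if (best == 0L) {
      cent_seq <- c(cent_seq, q)
      cent_len <- c(cent_len, lq)
      cent_founder_size <- c(cent_founder_size, zotus$size[i])
      cid <- length(cent_seq)
      for (km in qk) {
        kindex[[km]] <- c(kindex[[km]], cid)
      }
      assign_to[i] <- cid
    } else {
      assign_to[i] <- best
    }
  }
  otu_labels <- sprintf("OTU%04d", seq_along(cent_seq))
  m <- rowsum(unclass(zotus$table), group = otu_labels[assign_to],
              reorder = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  list(table = unit_table(m, kind = "OTU"),
       centroids = stats::setNames(cent_seq, otu_labels),
       membership = stats::setNames(otu_labels[assign_to], zotus$label))
}

#' De novo chimera flagging by two-parent breakpoint scan
#'
#' A zOTU is flagged as chimeric when two more-abundant parents (each with
#' at least `parent_ratio` times its size) admit a single-crossover
#' two-segment model differing from the query by at most
#' `max_chimera_diffs`, while the nearest single parent alone differs by at
#' least `min_div`. Candidate parents are screened by shared k-mers and
#' capped at `max_parents` per query.
#'
#' @param zotus A size-sorted `zotu_set`.
#' @param max_chimera_diffs Maximum differences of the best two-segment
#'   model to the query.
#' @param min_div Minimum differences of the nearest single parent.
#' @param parent_ratio Minimum parent/query abundance ratio.
#' @param max_parents Candidate parents retained after the k-mer screen.
#' @param min_shared_kmers Minimum shared k-mers for a candidate parent.
#' @return Logical vector, `TRUE` for flagged zOTUs.
#' @export
detect_chimeras <- function(zotus, max_chimera_diffs = 1L, min_div = 4L,
                            parent_ratio = 2, max_parents = 12L,
                            min_shared_kmers = 30L) {
  stopifnot(inherits(zotus, "zotu_set"))
  n <- length(zotus$seq)
  flag <- logical(n)
  if (n < 3L) return(flag)
  k <- 8L
  km <- lapply(zotus$seq, .kmers, k = k)
  # inverted index over the growing parent pool: k-mer -> pool positions.
  # eligibility (earlier, unflagged, >= parent_ratio x query size) is
  # monotone in the processing order, so parents are added lazily once
  kindex <- new.env(parent = emptyenv(), hash = TRUE)
  pool_ids <- integer(0)   # zOTU indices in the pool, in insertion order
  next_j <- 1L
  profile_of <- function(i, j) {
    band <- abs(nchar(zotus$seq[i]) - nchar(zotus$seq[j])) + 32L
    .ovl_diff_profile(zotus$seq[i], zotus$seq[j], band = band)
  }
  for (i in 2:n) {
    while (next_j < i &&
           zotus$size[next_j] >= parent_ratio * zotus$size[i]) {
      if (!flag[next_j]) {
        pool_ids <- c(pool_ids, next_j)
        pid <- length(pool_ids)
        for (kmer in km[[next_j]]) {
          kindex[[kmer]] <- c(kindex[[kmer]], pid)
        }
      }
      next_j <- next_j + 1L
    }
    if (length(pool_ids) < 2L) next
    qk <- km[[i]]
    lq <- nchar(zotus$seq[i])
    hits <- mget(qk, envir = kindex, ifnotfound = list(integer(0)))
    shared <- tabulate(unlist(hits, use.names = FALSE),
                       nbins = length(pool_ids))
    covered <- sum(lengths(hits) > 0L)
    # a two-segment model within max_chimera_diffs leaves at most
    # k*(max_chimera_diffs + 1) query k-mers outside the parents' union
    if (covered < length(qk) - k * (max_chimera_diffs + 1L)) next
    cand <- which(shared >= min_shared_kmers)
    if (length(cand) < 2L) next
    cand <- cand[order(-shared[cand])]
    if (length(cand) > max_parents) cand <- cand[seq_len(max_parents)]
    # nearest-parent early exit: only parents sharing almost every k-mer
    # can lie within min_div differences; check those first
    prof <- vector("list", length(cand))
    near <- FALSE
    for (a in seq_along(cand)) {
      if (shared[cand[a]] < length(qk) - k * min_div) break
      prof[[a]] <- profile_of(i, pool_ids[cand[a]])
      if (prof[[a]][lq] < min_div) {
        near <- TRUE
        break
      }
    }
    if (near) next
    for (a in seq_along(cand)) {
      if (is.null(prof[[a]])) prof[[a]] <- profile_of(i, pool_ids[cand[a]])
    }
    totals <- vapply(prof, function(p) p[lq], integer(1))
    if (min(totals) < min_div) next
    best_model <- Inf
    for (a in seq_along(cand)) {
      for (b in seq_along(cand)) {
        if (a == b) next
        da <- prof[[a]]
        db <- prof[[b]]
        model <- min(da[-lq] + db[lq] - db[-lq])
        if (model < best_model) best_model <- model
        if (best_model <= max_chimera_diffs) break
      }
      if (best_model <= max_chimera_diffs) break
    }
    flag[i] <- best_model <= max_chimera_diffs
  }
  flag
}

#' Build a LULU match list over centroid sequences
#'
#' All ordered centroid pairs whose pairwise identity reaches `min_match`
#' percent, with identities reported as percentages; no self-matches.
#'
#' @param centroids Named character vector (unit label -> sequence).
#' @param min_match Minimum percent identity retained (default 84).
#' @return data.frame with columns `query`, `target`, `pident`.
#' @export
build_match_list <- function(centroids, min_match = 84) {
  labs <- names(centroids)
  empty <- data.frame(query = character(), target = character(),
                      pident = numeric(), stringsAsFactors = FALSE)
  n <- length(centroids)
  if (n < 2L) return(empty)
  t <- min_match / 100
  rows_q <- character(0); rows_t <- character(0); rows_p <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dmax <- .max_diffs_for(t, nchar(centroids[i]), nchar(centroids[j]))
      ident <- .identity_banded(centroids[[i]], centroids[[j]], dmax)
      if (ident * 100 >= min_match) {
        rows_q <- c(rows_q, labs[i], labs[j])
        rows_t <- c(rows_t, labs[j], labs[i])
        rows_p <- c(rows_p, ident * 100, ident * 100)
      }
    }
  }
  data.frame(query = rows_q, target = rows_t, pident = rows_p,
             stringsAsFactors = FALSE)
}

#' LULU-style post-clustering curation
#'
#' Iterating daughters from least to most abundant, a daughter unit is
#' merged into its best matching more-abundant parent when the match-list
#' identity reaches the list's cutoff, the parent is present in at least
#' `min_cooccurrence` of the daughter's occupied samples, and the
#' parent/daughter abundance ratio is at least `min_ratio` in each of those
#' co-occurring samples. Merged counts are added to the parent row, so total
#' counts are conserved.
#'
#' @param table A [unit_table].
#' @param matches Match list from [build_match_list].
#' @param min_ratio Minimum per-sample parent/daughter ratio (default 1).
#' @param min_cooccurrence Minimum fraction of the daughter's occupied
#'   samples in which the parent occurs (default 0.95).
#' @return List with `table` (the curated [unit_table]) and `log` (a
#'   data.frame of merges: `daughter`, `parent`, `pident`).
#' @export
lulu_curate <- function(table, matches, min_ratio = 1,
                        min_cooccurrence = 0.95) {
  stopifnot(inherits(table, "unit_table"))
  kind <- attr(table, "kind")
  m <- unclass(table)
  log <- data.frame(daughter = character(), parent = character(),
                    pident = numeric(), stringsAsFactors = FALSE)
  if (nrow(matches) == 0L || nrow(m) < 2L) {
    return(list(table = table, log = log))
  }
  totals <- rowSums(m)
  redirect <- stats::setNames(rownames(m), rownames(m))
  resolve <- function(u) {
    while (redirect[[u]] != u) u <- redirect[[u]]
    u
  }
  merged <- character(0)
  for (d in rownames(m)[order(totals, rownames(m))]) {
    cand <- matches[matches$query == d, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand$target <- vapply(cand$target, resolve, character(1))
    cand <- cand[cand$target != d & cand$target %in% rownames(m) &
                   !(cand$target %in% merged), , drop = FALSE]
    if (nrow(cand) == 0L) next
    occ <- which(m[d, ] > 0L)
    if (length(occ) == 0L) next
    ok <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      p <- cand$target[r]
      if (sum(m[p, ]) <= sum(m[d, ])) next
      co <- m[p, occ] > 0L
      if (mean(co) < min_cooccurrence) next
      if (any(co) && min(m[p, occ][co] / m[d, occ][co]) < min_ratio) next
      ok[r] <- TRUE
    }
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order(-cand$pident, -rowSums(m)[cand$target]), , drop = FALSE]
    p <- cand$target[1L]
    m[p, ] <- m[p, ] + m[d, ]
    m[d, ] <- 0L
    redirect[[d]] <- p
    merged <- c(merged, d)
    log <- rbind(log, data.frame(daughter = d, parent = p,
                                 pident = cand$pident[1L],
                                 stringsAsFactors = FALSE))
  }
  list(table = unit_table(m, kind = kind), log = log)
}
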