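#' Minimum-quality evaluation parameters
#'
#' Controls the per-Phred recovery experiment: reads are stratified into
#' integer mean-Phred bins, each bin is subsampled to a common depth (the
#' read count of the highest-quality bin in the source study design), the
#' chosen approach is run end-to-end, and the unit count is recorded with
#' and without singleton units, over replicates.
#'
#' @param q_range Two-element integer Phred bin interval (default 14-28).
#' @param depth Reads subsampled per bin and replicate.
#' @param n_rep Number of replicates per bin (default 100).
#' @param approach `"OTU"` (dereplicate, chimera-filter, greedy-cluster),
#'   `"SH"` (dereplicate, chimera-filter, classify, dual-threshold filter,
#'   aggregate) or `"zOTU"` (dereplicate only).
#' @param seed Master seed; replicate seeds are `seed + replicate`.
#' @return An object of class `eval_params`.
#' @export
eval_params <- function(q_range = c(14L, 28L), depth = 1000L, n_rep = 100L,
                        approach = c("OTU", "SH", "zOTU"), seed = 1L) {
  approach <- match.arg(approach)
  stopifnot(length(q_range) == 2L, q_range[1] <= q_range[2],
            depth >= 1L, n_rep >= 1L)
  structure(list(q_range = as.integer(q_range), depth = as.integer(depth),
                 n_rep = as.integer(n_rep), approach = approach,
                 seed = as.integer(seed)),
            class = "eval_params")
}

.run_approach <- function(sub, approach, db, cluster_p, classify_p,
                          rep_seed) {
  z <- dereplicate(sub)
  if (approach == "zOTU") {
    tab <- z$table
    return(list(table = tab, frac_classified = NA_real_))
  }
  flags <- detect_chimeras(z)
  z <- zotu_subset(z, !flags)
  if (approach == "OTU") {
    cl <- greedy_cluster(z, cluster_p)
    return(list(table = cl$table, frac_classified = NA_real_))
  }
  # SH approach
  cp <- classify_p
  cp$seed <- as.integer(rep_seed)
  cls <- classify_zotus(z$seq, db, cp)
  keep <- apply_confidence_filter(z$size, cls$conf_species, cp)
  frac <- if (sum(z$size) > 0) sum(z$size[keep]) / sum(z$size) else NA_real_
  if (!any(keep)) {
    empty <- unit_table(matrix(integer(0), nrow = 0,
                               ncol = ncol(z$table),
                               dimnames = list(NULL, colnames(z$table))),
                        kind = "SH")
    return(list(table = empty, frac_classified = frac))
  }
  kept <- zotu_subset(z, keep)
  tab <- aggregate_sh(kept$table, cls$species[keep])
  list(table = tab, frac_classified = frac)
}

#' Per-Phred taxonomic-unit recovery with replication
#'
#' For every integer Phred bin in `q_range` and every replicate, subsamples
#' the bin to `depth` reads with the replicate seed, runs the chosen
#' approach end-to-end and records the number of recovered units with and
#' without singleton units (and, for the SH approach, the classified read
#' fraction).
#'
#' @param reads Trimmed, oriented [quality_reads] covering the bin range.
#' @param db A [reference_db]; required for the SH approach.
#' @param params An [eval_params].
#' @param cluster_p A [cluster_params] (OTU approach).
#' @param classify_p A [classify_params] (SH approach).
#' @return An object of class `recovery_curve` wrapping a long data.frame
#'   (`approach`, `q_bin`, `replicate`, `n_units_all`,
#'   `n_units_no_singletons`, `frac_classified`).
#' @export
recovery_curve <- function(reads, db = NULL, params = eval_params(),
                           cluster_p = cluster_params(),
                           classify_p = classify_params()) {
  stopifnot(inherits(params, "eval_params"))
  if (params$approach == "SH" && is.null(db)) {
    stop("recovery_curve: the SH approach requires a reference database")
  }
  if (!is.null(db) && (is.null(db$index) || db$index$k != classify_p$k)) {
    db <- build_kmer_index(db, classify_p$k)
  }
  bins <- params$q_range[1]:params$q_range[2]
  strata <- stratify_by_phred(reads, params$q_range[1], params$q_range[2])
  short <- bins[vapply(strata, length, integer(1)) < params$depth]
  if (length(short) > 0L) {
    stop(sprintf("recovery_curve: bin Q%d holds fewer than %d reads",
                 short[1L], params$depth))
  }
  rows <- vector("list", length(bins) * params$n_rep)
  ix <- 0L
  for (q in bins) {
    bin_reads <- strata[[as.character(q)]]
    for (r in seq_len(params$n_rep)) {
      rep_seed <- params$seed + r
      sub <- subsample(bin_reads, params$depth, seed = rep_seed + 131L * q)
      res <- .run_approach(sub, params$approach, db, cluster_p, classify_p,
                           rep_seed + 131L * q)
      tab <- res$table
      ix <- ix + 1L
      rows[[ix]] <- data.frame(
        approach = params$approach, q_bin = q, replicate = r,
        n_units_all = nrow(tab),
        n_units_no_singletons = sum(rowSums(tab) >= 2L),
        frac_classified = res$frac_classified,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(data = do.call(rbind, rows), params = params),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %s approach, bins Q%d-Q%d, %d replicate(s), depth %d\n",
              x$params$approach, x$params$q_range[1], x$params$q_range[2],
              x$params$n_rep, x$params$depth))
  print(summary(x))
  invisible(x)
}

#' Per-bin summary of a recovery curve
#'
#' @param object A `recovery_curve`.
#' @param ... Unused.
#' @return data.frame with per-bin mean and sd of unit counts, with and
#'   without singleton units.
#' @export
summary.recovery_curve <- function(object, ...) {
  d <- object$data
  agg <- function(v) {
    m <- tapply(v, d$q_bin, mean)
    s <- tapply(v, d$q_bin, stats::sd)
    list(mean = as.numeric(m), sd = as.numeric(s),
         q = as.integer(names(m)))
  }
  a <- agg(d$n_units_all)
  b <- agg(d$n_units_no_singletons)
  data.frame(q_bin = a$q, mean_all = a$mean, sd_all = a$sd,
             mean_no_singletons = b$mean, sd_no_singletons = b$sd)
}

#' Plot a recovery curve
#'
#' Replicate unit counts per Phred bin with a loess smoother as a visual
#' aid (the smoother plays no part in stabilization detection).
#'
#' @param x A `recovery_curve`.
#' @param singletons `"all"` or `"no_singletons"`.
#' @param ... Passed to [plot()].
#' @export
plot.recovery_curve <- function(x, singletons = c("all", "no_singletons"),
                                ...) {
  singletons <- match.arg(singletons)
  d <- x$data
  y <- if (singletons == "all") d$n_units_all else d$n_units_no_singletons
  plot(jitter(d$q_bin, 0.3), y, xlab = "mean Phred bin",
       ylab = sprintf("recovered %s units (%s)", x$params$approach,
                      singletons),
       pch = 16, col = grDevices::adjustcolor("steelblue", 0.5), ...)
  if (length(unique(d$q_bin)) >= 4L) {
    lo <- stats::loess(y ~ qb, data = data.frame(qb = d$q_bin, y = y))
    qs <- sort(unique(d$q_bin))
    graphics::lines(qs, stats::predict(lo, data.frame(qb = qs)),
                    col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Write the long-form recovery curve as TSV
#'
#' @param curve A `recovery_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recovery_curve <- function(curve, path) {
  utils::write.table(curve$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detect the Phred score at which unit recovery stabilizes
#'
#' The smallest bin `Q*` such that for every consecutive bin pair inside
#' `[Q*, Q* + window]` the relative change in mean unit count,
#' `|mean(Q+1) - mean(Q)| / max(mean(Q), 1)`, is at most `epsilon`.
#'
#' @param curve A `recovery_curve`, or a named numeric vector of per-bin
#'   means (names = integer Phred bins).
#' @param window Number of consecutive bin pairs that must be flat.
#' @param epsilon Maximum relative change per pair.
#' @param singletons Which count to use when `curve` is a `recovery_curve`.
#' @return The integer `Q*`, or `NA` if the curve never stabilizes.
#' @export
detect_stabilization <- function(curve, window = 3L, epsilon = 0.05,
                                 singletons = c("all", "no_singletons")) {
  if (inherits(curve, "recovery_curve")) {
    singletons <- match.arg(singletons)
    s <- summary(curve)
    means <- if (singletons == "all") s$mean_all else s$mean_no_singletons
    names(means) <- s$q_bin
  } else {
    means <- curve
    if (is.null(names(means))) {
      stop("detect_stabilization: per-bin means must be named by Phred bin")
    }
  }
  q <- as.integer(names(means))
  o <- order(q)
  q <- q[o]
  means <- as.numeric(means)[o]
  nb <- length(means)
  if (nb < window + 1L) {
    stop("detect_stabilization: curve must span at least window + 1 bins")
  }
  rel <- abs(diff(means)) / pmax(means[-nb], 1)
  for (i in seq_len(nb - window)) {
    if (all(rel[i:(i + window - 1L)] <= epsilon)) return(q[i])
  }
  NA_integer_
}

#' Mean classified-read fraction per Phred bin
#'
#' Runs the SH approach per bin and replicate and averages the
#' dual-threshold classified read fraction.
#'
#' @inheritParams recovery_curve
#' @return data.frame with `q_bin`, `mean_rate`, `sd_rate`.
#' @export
classification_rate_curve <- function(reads, db, params = eval_params(),
                                      classify_p = classify_params()) {
  params$approach <- "SH"
  rc <- recovery_curve(reads, db, params, classify_p = classify_p)
  d <- rc$data
  m <- tapply(d$frac_classified, d$q_bin, mean)
  s <- tapply(d$frac_classified, d$q_bin, stats::sd)
  data.frame(q_bin = as.integer(names(m)), mean_rate = as.numeric(m),
             sd_rate = as.numeric(s))
}

#' Fraction of reads held in singleton units
#'
#' @param table A non-empty [unit_table].
#' @return Fraction of the grand total held in rows whose total is 1.
#' @export
singleton_fraction <- function(table) {
  stopifnot(inherits(table, "unit_table"))
  total <- sum(table)
  if (nrow(table) == 0L || total == 0L) {
    stop("singleton_fraction: empty unit table")
  }
  sum(rowSums(table) == 1L) / total
}
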