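#' Mock-community specification
#'
#' Describes the synthetic reference community the simulator builds: a
#' phylogenetically diverse set of taxa of which some may be near-neighbour
#' pairs diverging by less than a clustering radius. The defaults emulate a
#' 16-taxon ectomycorrhizal mock community with full-ITS amplicon interiors
#' of roughly 650-780 bp.
#'
#' @param n_taxa Number of references (>= 1).
#' @param length_range Two-element bp interval for reference lengths.
#' @param near_pairs List of `c(divergence, count)` entries: `count`
#'   references are created as mutated copies of existing references at the
#'   stated pairwise divergence fraction (each in (0, 0.1]).
#' @param abundance_profile Per-taxon expected read fractions summing to 1;
#'   default uniform.
#' @param seed Integer seed governing reference construction.
#' @return An object of class `mock_spec`.
#' @export
mock_spec <- function(n_taxa = 16L, length_range = c(650L, 780L),
                      near_pairs = list(), abundance_profile = NULL,
                      seed = 1L) {
  stopifnot(n_taxa >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2], length_range[1] >= 50L)
  for (np in near_pairs) {
    stopifnot(length(np) == 2L, np[1] > 0, np[1] <= 0.1, np[2] >= 1)
  }
  n_paired <- if (length(near_pairs)) sum(vapply(near_pairs, `[`, numeric(1), 2)) else 0L
  if (n_paired >= n_taxa) {
    stop("mock_spec: near-pair members must be fewer than n_taxa")
  }
  if (is.null(abundance_profile)) {
    abundance_profile <- rep(1 / n_taxa, n_taxa)
  }
  stopifnot(length(abundance_profile) == n_taxa,
            abs(sum(abundance_profile) - 1) < 1e-8,
            all(abundance_profile >= 0))
  structure(list(n_taxa = as.integer(n_taxa),
                 length_range = as.integer(length_range),
                 near_pairs = near_pairs,
                 abundance_profile = abundance_profile,
                 seed = as.integer(seed)),
            class = "mock_spec")
}

#' Nanopore-like error model
#'
#' Error class mix (substitution/insertion/deletion fractions, summing to 1)
#' and the per-base Phred spread around a read's target mean quality.
#'
#' @param sub_fraction,ins_fraction,del_fraction Non-negative class
#'   fractions summing to 1.
#' @param qual_spread Standard deviation (Phred units) of per-base quality
#'   around the read's target mean.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_fraction = 0.5, ins_fraction = 0.25,
                        del_fraction = 0.25, qual_spread = 3) {
  stopifnot(sub_fraction >= 0, ins_fraction >= 0, del_fraction >= 0,
            abs(sub_fraction + ins_fraction + del_fraction - 1) < 1e-9,
            qual_spread >= 0)
  structure(list(sub_fraction = sub_fraction, ins_fraction = ins_fraction,
                 del_fraction = del_fraction, qual_spread = qual_spread),
            class = "error_model")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly `d` distinct positions with different bases
.mutate_subs <- function(seq, d) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(ch), d)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

.dummy_lineage <- function(i) {
  c(d = "Fungi", p = "Basidiomycota", c = "Agaricomycetes",
    o = sprintf("Ord%02d", ceiling(i / 4)),
    f = sprintf("Fam%02d", ceiling(i / 2)),
    g = sprintf("Gen%02d", i),
    s = sprintf("SH%07d.10FU", i))
}

#' Generate a mock-community reference set
#'
#' Builds `n_taxa` ITS-like references: uniform random nucleotides around a
#' shared 150 bp conserved core (a 5.8S-like region), so that cross-taxon
#' chimeras and k-mer classification face realistic shared signal. For each
#' near-pair entry an existing reference is duplicated and mutated by exact
#' substitutions to the stated divergence. Every reference carries a 7-rank
#' dummy lineage ending in a dummy species-hypothesis code
#' (`SH0000001.10FU` style); near-pair partners share their source's lineage
#' through genus but receive their own SH.
#'
#' @param spec A [mock_spec].
#' @return A [reference_db] object.
#' @export
generate_reference_set <- function(spec) {
  stopifnot(inherits(spec, "mock_spec"))
  .with_seed(spec$seed, {
    core_len <- min(150L, floor(spec$length_range[1] / 3))
    core <- .rand_dna(core_len)
    pair_counts <- vapply(spec$near_pairs, `[`, numeric(1), 2)
    n_partner <- if (length(pair_counts)) as.integer(sum(pair_counts)) else 0L
    n_base <- spec$n_taxa - n_partner
    seqs <- character(spec$n_taxa)
    lineages <- vector("list", spec$n_taxa)
    for (i in seq_len(n_base)) {
      len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
      rest <- len - core_len
      pre <- floor(rest * 0.4)
      seqs[i] <- paste0(.rand_dna(pre), core, .rand_dna(rest - pre))
      lineages[[i]] <- .dummy_lineage(i)
    }
    slot <- n_base
    src <- 0L
    for (np in spec$near_pairs) {
      for (j in seq_len(np[2])) {
        src <- src + 1L
        slot <- slot + 1L
        L <- nchar(seqs[src])
        d <- round(np[1] * L)
        if (d < 1L) {
          stop(sprintf(
            "generate_reference_set: divergence %.4f unreachable at length %d",
            np[1], L))
        }
        seqs[slot] <- .mutate_subs(seqs[src], d)
        lin <- lineages[[src]]
        lin["s"] <- sprintf("SH%07d.10FU", slot)
        lineages[[slot]] <- lin
      }
    }
    reference_db(sprintf("REF%03d", seq_len(spec$n_taxa)), seqs, lineages)
  })
}

#' Per-base quality string at a controlled mean Phred
#'
#' Draws per-base Phred values as `round(rnorm(length, mu, spread))` clipped
#' to \[2, 50\], choosing `mu` by bisection so that the probability-domain
#' mean Phred of the result (see [mean_phred]) lies within 0.5 of
#' `target_mean_q`. With `qual_spread = 0` every base gets the rounded
#' target.
#'
#' @param target_mean_q Target mean Phred in \[2, 50\].
#' @param length Number of bases.
#' @param model An [error_model] (supplies `qual_spread`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer Phred vector of the requested length.
#' @export
make_quality_string <- function(target_mean_q, length, model = error_model(),
                                seed = NULL) {
  stopifnot(target_mean_q >= 2, target_mean_q <= 50, length >= 1)
  gen <- function() {
    if (model$qual_spread == 0) {
      return(rep(as.integer(round(target_mean_q)), length))
    }
    z <- stats::rnorm(length, 0, model$qual_spread)
    f <- function(cc) mean_phred(pmin(pmax(round(z + cc), 2), 50))
    lo <- 0; hi <- 60
    for (it in 1:48) {
      mid <- (lo + hi) / 2
      if (f(mid) < target_mean_q) lo <- mid else hi <- mid
    }
    cand <- vapply(c(lo, hi), f, numeric(1))
    cc <- c(lo, hi)[which.min(abs(cand - target_mean_q))]
    as.integer(pmin(pmax(round(z + cc), 2), 50))
  }
  q <- if (is.null(seed)) gen() else .with_seed(seed, gen())
  if (abs(mean_phred(q) - target_mean_q) > 0.5) {
    stop("make_quality_string: could not reach target mean quality")
  }
  q
}

# inject quality-conditioned errors into one template; returns list(seq,
# quals, n_errors)
.inject_errors <- function(template, quals, model, target_q) {
  p <- 10^(-quals / 10)
  hit <- which(stats::runif(length(p)) < p)
  if (length(hit) == 0L) {
    return(list(seq = template, quals = quals, n_errors = 0L))
  }
  cls <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                prob = c(model$sub_fraction, model$ins_fraction,
                         model$del_fraction))
  ch <- strsplit(template, "", fixed = TRUE)[[1L]]
  q <- quals
  ins_q <- as.integer(min(max(round(target_q), 2), 50))
  for (k in rev(seq_along(hit))) {  # descending positions keep indices valid
    pos <- hit[k]
    if (cls[k] == "sub") {
      ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
    } else if (cls[k] == "ins") {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = pos)
      q <- append(q, ins_q, after = pos)
    } else {
      ch <- ch[-pos]
      q <- q[-pos]
    }
  }
  list(seq = paste(ch, collapse = ""), quals = q, n_errors = length(hit))
}

#' Simulate Nanopore-like amplicon reads with ground truth
#'
#' Each read copies one reference (or, with probability `chimera_rate`, a
#' single-breakpoint two-parent chimera with the breakpoint uniform in the
#' middle 80% of the amplicon), receives forward/reverse primer flanks, a
#' per-base quality string at its target mean Phred, and per-base errors at
#' rate `10^(-q/10)` with the class drawn from the error model. Half the
#' reads are emitted reverse-complemented so that primer reorientation is
#' exercised. Quality targets are allocated to reads by even recycling of
#' `quality_targets`, so per-target read counts are exact.
#'
#' @param db A [reference_db] from [generate_reference_set].
#' @param spec The [mock_spec] (supplies the abundance profile).
#' @param n_reads Number of reads to emit.
#' @param quality_targets Vector of target mean Phred scores, recycled
#'   across reads.
#' @param chimera_rate Fraction of reads simulated as chimeras, in \[0, 1\].
#' @param model An [error_model].
#' @param seed Integer seed; the same seed yields byte-identical FASTQ.
#' @param primers A [primer_pair] whose sequences flank each amplicon.
#' @param sample Sample label for all reads.
#' @return List with `reads` (a [quality_reads]) and `truth` (a data.frame
#'   with one row per read: `read_id`, `taxon`, `is_chimera`, `parent_a`,
#'   `parent_b`, `breakpoint`, `n_errors`).
#' @export
simulate_reads <- function(db, spec, n_reads, quality_targets = 20,
                           chimera_rate = 0, model = error_model(),
                           seed = 1L, primers = primer_pair(),
                           sample = "s1") {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$accession) == 0L) stop("simulate_reads: empty reference set")
  stopifnot(chimera_rate >= 0, chimera_rate <= 1, n_reads >= 1)
  fwd <- primers$forward
  rc_rev <- .revcomp(primers$reverse)
  targets <- rep_len(as.numeric(quality_targets), n_reads)
  nref <- length(db$accession)
  .with_seed(seed, {
    ids <- sprintf("read%06d", seq_len(n_reads))
    seqs <- character(n_reads)
    quals <- vector("list", n_reads)
    taxon <- character(n_reads)
    is_chim <- logical(n_reads)
    par_a <- par_b <- rep(NA_character_, n_reads)
    brk <- rep(NA_integer_, n_reads)
    nerr <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      if (stats::runif(1) < chimera_rate && nref >= 2L) {
        pp <- sample.int(nref, 2L)
        fa <- stats::runif(1, 0.1, 0.9)
        la <- nchar(db$seq[pp[1]]); lb <- nchar(db$seq[pp[2]])
        cut_a <- round(fa * la)
        template <- paste0(substr(db$seq[pp[1]], 1L, cut_a),
                           substr(db$seq[pp[2]], round(fa * lb) + 1L, lb))
        is_chim[i] <- TRUE
        par_a[i] <- db$accession[pp[1]]
        par_b[i] <- db$accession[pp[2]]
        brk[i] <- cut_a
        taxon[i] <- NA_character_
      } else {
        t_idx <- sample.int(nref, 1L, prob = spec$abundance_profile)
        template <- db$seq[t_idx]
        taxon[i] <- db$accession[t_idx]
      }
      amplicon <- paste0(fwd, template, rc_rev)
      qv <- make_quality_string(targets[i], nchar(amplicon), model)
      er <- .inject_errors(amplicon, qv, model, targets[i])
      if (stats::runif(1) < 0.5) {
        seqs[i] <- .revcomp(er$seq)
        quals[[i]] <- rev(er$quals)
      } else {
        seqs[i] <- er$seq
        quals[[i]] <- er$quals
      }
      nerr[i] <- er$n_errors
    }
    list(reads = quality_reads(ids, seqs, quals, sample),
         truth = data.frame(read_id = ids, taxon = taxon,
                            is_chimera = is_chim, parent_a = par_a,
                            parent_b = par_b, breakpoint = brk,
                            n_errors = nerr, stringsAsFactors = FALSE))
  })
}

#' Write a ground-truth table as TSV
#'
#' @param truth The `truth` data.frame from [simulate_reads].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
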