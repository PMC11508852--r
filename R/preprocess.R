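#' PCR primer pair for reorientation and trimming
#'
#' Defaults are the full-ITS primer pair ITS1F/ITS4 commonly used for fungal
#' long-read amplicons; both may contain IUPAC ambiguity codes.
#'
#' @param forward,reverse Primer sequences, 5'->3' on their own strands.
#' @param max_mismatch Maximum edit distance (substitutions + indels) allowed
#'   when locating each primer; must be smaller than the primer length.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward = "CTTGGTCATTTAGAGGAAGTAA",
                        reverse = "TCCTCCGCTTATTGATATGC",
                        max_mismatch = 3L) {
  stopifnot(nchar(forward) > 0, nchar(reverse) > 0,
            max_mismatch < min(nchar(forward), nchar(reverse)))
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

.str_rev <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# best semi-global primer hit in the first `w` bases of each sequence:
# returns cbind(dist, end-position-in-read)
.primer_hit_head <- function(seqs, primer, w) {
  .primer_search(substr(seqs, 1L, w), primer)
}

# best hit of `primer` in the last `w` bases; returns cbind(dist, start
# position in the read)
.primer_hit_tail <- function(seqs, primer, w) {
  n <- nchar(seqs)
  lo <- pmax(1L, n - w + 1L)
  sfx <- substring(seqs, lo, n)
  hit <- .primer_search(.str_rev(sfx), .str_rev(primer))
  start <- n - hit[, "end"] + 1L
  cbind(dist = hit[, "dist"], start = start)
}

#' Reorient reads and trim primer flanks
#'
#' Each read is reverse-complemented when the forward primer matches the
#' reverse strand better, then both primer flanks are located by IUPAC-aware
#' semi-global alignment and removed, with qualities trimmed in lockstep.
#' Reads in which either primer cannot be found within `max_mismatch` edits
#' are rejected with a reason code, never silently dropped.
#'
#' @param reads A [quality_reads] object.
#' @param primers A [primer_pair].
#' @param window_slack Extra bases beyond the primer length searched at each
#'   read end (accommodates indels and small offsets).
#' @return A list with components `reads` (the kept, trimmed
#'   [quality_reads]) and `log` (a data.frame with columns `read_id`,
#'   `action`, `reason`, `flipped`).
#' @export
trim_and_orient <- function(reads, primers = primer_pair(),
                            window_slack = 10L) {
  stopifnot(inherits(reads, "quality_reads"), inherits(primers, "primer_pair"))
  n <- length(reads)
  if (n == 0L) {
    return(list(reads = reads,
                log = data.frame(read_id = character(), action = character(),
                                 reason = character(), flipped = logical())))
  }
  fwd <- primers$forward
  rc_rev <- .revcomp(primers$reverse)
  wf <- nchar(fwd) + window_slack
  wr <- nchar(rc_rev) + window_slack

  # orientation: forward primer fit at the head of each strand
  d_plus <- .primer_hit_head(reads$seq, fwd, wf)[, "dist"]
  rc_seq <- .revcomp(reads$seq)
  d_minus <- .primer_hit_head(rc_seq, fwd, wf)[, "dist"]
  flip <- d_minus < d_plus
  seqs <- ifelse(flip, rc_seq, reads$seq)
  quals <- reads$quals
  quals[flip] <- lapply(quals[flip], rev)

  hf <- .primer_hit_head(seqs, fwd, wf)
  hr <- .primer_hit_tail(seqs, rc_rev, wr)
  mm <- primers$max_mismatch
  ok_f <- hf[, "dist"] <= mm
  ok_r <- hr[, "dist"] <= mm
  interior_lo <- hf[, "end"] + 1L
  interior_hi <- hr[, "start"] - 1L
  nonempty <- interior_hi >= interior_lo
  keep <- ok_f & ok_r & nonempty

  reason <- rep("", n)
  reason[!ok_f & !ok_r] <- "no_primers"
  reason[!ok_f & ok_r] <- "no_forward_primer"
  reason[ok_f & !ok_r] <- "no_reverse_primer"
  reason[ok_f & ok_r & !nonempty] <- "empty_interior"

  log <- data.frame(read_id = reads$id,
                    action = ifelse(keep, "kept", "rejected"),
                    reason = reason, flipped = flip,
                    stringsAsFactors = FALSE)
  idx <- which(keep)
  trimmed <- quality_reads(
    reads$id[idx],
    substring(seqs[idx], interior_lo[idx], interior_hi[idx]),
    lapply(idx, function(i) quals[[i]][interior_lo[i]:interior_hi[i]]),
    reads$sample[idx]
  )
  list(reads = trimmed, log = log)
}

#' Stratify reads into integer Phred bins
#'
#' Reads are assigned to the bin `round(mean Phred)` using round-half-up;
#' reads outside `[q_min, q_max]` are dropped. The returned bins partition
#' the retained reads.
#'
#' @param reads A [quality_reads] object.
#' @param q_min,q_max Inclusive integer bin range.
#' @return Named list (names = bin as character) of [quality_reads], one
#'   entry per bin in `q_min:q_max` (possibly empty).
#' @export
stratify_by_phred <- function(reads, q_min, q_max) {
  stopifnot(q_min <= q_max)
  mq <- read_mean_phred(reads)
  bin <- floor(mq + 0.5)  # round half up
  out <- lapply(q_min:q_max, function(q) reads[which(bin == q)])
  names(out) <- as.character(q_min:q_max)
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Seeded uniform subsampling without replacement
#'
#' Draws exactly `depth` reads uniformly without replacement; the selection
#' is deterministic for a fixed seed and returned in original read order.
#'
#' @param reads A [quality_reads] object.
#' @param depth Number of reads to keep; must not exceed `length(reads)`.
#' @param seed Integer seed.
#' @return A [quality_reads] object with `depth` reads.
#' @export
subsample <- function(reads, depth, seed = 1L) {
  stopifnot(inherits(reads, "quality_reads"))
  if (depth > length(reads)) {
    stop(sprintf("subsample: depth %d exceeds available reads (%d)",
                 depth, length(reads)))
  }
  idx <- .with_seed(seed, sort(sample.int(length(reads), depth)))
  reads[idx]
}
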