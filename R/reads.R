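#' Quality-annotated read sets
#'
#' A `quality_reads` object holds amplicon reads as parallel vectors: read
#' ids, nucleotide sequences, per-base Phred quality vectors (a list of
#' integer vectors) and a sample label per read. It supports `length()`,
#' subsetting with `[`, and concatenation with `c()`.
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @param quals List of integer Phred vectors, one per read, each the same
#'   length as its sequence, values in \[0, 93\].
#' @param sample Sample label(s), recycled to the number of reads.
#' @return An object of class `quality_reads`.
#' @export
quality_reads <- function(id, seq, quals, sample = "s1") {
  n <- length(id)
  stopifnot(length(seq) == n, length(quals) == n)
  lens_ok <- vapply(seq_len(n), function(i) {
    length(quals[[i]]) == nchar(seq[i])
  }, logical(1))
  if (!all(lens_ok)) {
    bad <- id[which(!lens_ok)[1L]]
    stop(sprintf("quality_reads: sequence/quality length mismatch in record '%s'", bad))
  }
  rng <- if (n > 0) range(unlist(quals, use.names = FALSE)) else c(0L, 0L)
  if (n > 0 && (rng[1] < 0 || rng[2] > 93)) {
    stop("quality_reads: Phred values must lie in [0, 93]")
  }
  structure(
    list(id = as.character(id), seq = toupper(as.character(seq)),
         quals = lapply(quals, as.integer),
         sample = rep_len(as.character(sample), n)),
    class = "quality_reads"
  )
}

#' @export
length.quality_reads <- function(x) length(x$id)

#' @export
`[.quality_reads` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], quals = x$quals[i],
                 sample = x$sample[i]),
            class = "quality_reads")
}

#' @export
c.quality_reads <- function(...) {
  parts <- list(...)
  structure(
    list(id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
         seq = unlist(lapply(parts, `[[`, "seq"), use.names = FALSE),
         quals = do.call(c, lapply(parts, `[[`, "quals")),
         sample = unlist(lapply(parts, `[[`, "sample"), use.names = FALSE)),
    class = "quality_reads"
  )
}

#' @export
print.quality_reads <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<quality_reads> %d read(s), %d sample(s)\n",
              n, length(unique(x$sample))))
  if (n > 0) {
    mq <- read_mean_phred(x)
    cat(sprintf("  length: %d-%d bp; mean Phred: %.1f-%.1f\n",
                min(nchar(x$seq)), max(nchar(x$seq)), min(mq), max(mq)))
  }
  invisible(x)
}

#' Per-read probability-domain mean Phred scores
#'
#' @param reads A [quality_reads] object.
#' @return Numeric vector of mean Phred scores, one per read.
#' @export
read_mean_phred <- function(reads) {
  vapply(reads$quals, mean_phred, numeric(1))
}

#' Read and write 4-line FASTQ (Phred+33)
#'
#' `read_fastq()` parses a plain 4-line-per-record FASTQ file into a
#' [quality_reads] object; `write_fastq()` is its inverse. A record whose
#' sequence and quality strings differ in length raises an error naming the
#' record. Writing uses a bare `+` separator line, so write/read/write
#' round-trips are byte-identical.
#'
#' @param path File path.
#' @param sample Sample label attached to every read.
#' @param reads A [quality_reads] object.
#' @return `read_fastq()` returns a [quality_reads] object; `write_fastq()`
#'   returns `path` invisibly.
#' @export
read_fastq <- function(path, sample = "s1") {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(quality_reads(character(), character(), list(), sample))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("read_fastq: '%s' is not 4-line FASTQ (%d lines)",
                 path, length(lines)))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  if (!all(startsWith(hdr, "@"))) {
    stop(sprintf("read_fastq: malformed header at record %d of '%s'",
                 which(!startsWith(hdr, "@"))[1L], path))
  }
  if (!all(startsWith(lines[idx + 2L], "+"))) {
    stop(sprintf("read_fastq: malformed separator at record %d of '%s'",
                 which(!startsWith(lines[idx + 2L], "+"))[1L], path))
  }
  ids <- substring(hdr, 2L)
  seqs <- lines[idx + 1L]
  qstr <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(qstr))
  if (length(bad) > 0L) {
    stop(sprintf("read_fastq: sequence/quality length mismatch in record '%s'",
                 ids[bad[1L]]))
  }
  quals <- lapply(qstr, function(s) utf8ToInt(s) - 33L)
  quality_reads(ids, seqs, quals, sample)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "quality_reads"))
  qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
  out <- character(4L * length(reads))
  if (length(reads) > 0) {
    idx <- seq(1L, length(out), by = 4L)
    out[idx] <- paste0("@", reads$id)
    out[idx + 1L] <- reads$seq
    out[idx + 2L] <- "+"
    out[idx + 3L] <- qstr
  }
  writeLines(out, path)
  invisible(path)
}

#' Trim leading bases from reads
#'
#' Removes the first `n_bases` positions from sequence and qualities in
#' lockstep. Trimming a low-quality head raises the probability-domain mean
#' Phred score of the remainder.
#'
#' @param reads A [quality_reads] object.
#' @param n_bases Number of leading bases to drop; must be smaller than every
#'   read length.
#' @return The trimmed [quality_reads] object.
#' @export
head_trim <- function(reads, n_bases) {
  stopifnot(inherits(reads, "quality_reads"), n_bases >= 0)
  if (n_bases == 0L) return(reads)
  if (any(nchar(reads$seq) <= n_bases)) {
    stop("head_trim: n_bases must be smaller than every read length")
  }
  reads$seq <- substring(reads$seq, n_bases + 1L)
  reads$quals <- lapply(reads$quals, function(q) q[-seq_len(n_bases)])
  reads
}
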