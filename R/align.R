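#' Pairwise sequence identity under global alignment
#'
#' Aligns two sequences end to end with an affine-gap global (Gotoh) aligner
#' (match +2, mismatch -4, gap open -10, gap extend -1) and returns identity
#' as matching columns divided by alignment columns, terminal gap runs
#' excluded from the denominator. Scoring end gaps (rather than leaving them
#' free) prevents degenerate short dovetail alignments from reporting
#' spuriously high identity between unrelated sequences. This is the
#' identity definition behind the package's greedy clustering threshold
#' (`--id` in the pipeline).
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' x <- strrep("ACGT", 25)
#' pairwise_identity(x, x)  # 1
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("pairwise_identity: sequences must be non-empty")
  }
  r <- .ovl_align(a, b)
  if (r[["columns"]] == 0L) return(0)
  r[["matches"]] / r[["columns"]]
}

# banded variant used in clustering inner loops: exact for pairs within
# `max_diffs` edits of each other; pairs farther apart can only be
# under-estimated, which never affects threshold decisions
.identity_banded <- function(a, b, max_diffs) {
  band <- as.integer(max_diffs + abs(nchar(a) - nchar(b)) + 5L)
  r <- .ovl_align(a, b, band = band)
  if (r[["columns"]] == 0L) return(0)
  r[["matches"]] / r[["columns"]]
}

.revcomp <- function(seq) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# unique k-mers of one sequence
.kmers <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# all k-mers (with positional multiplicity) of one sequence
.kmers_all <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, seq_len(n - k + 1L), k:n)
}
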