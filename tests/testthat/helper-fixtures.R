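# shared fixtures and independent oracles

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# substitute exactly `d` distinct positions (independent of package internals)
mutate_positions <- function(seq, pos, seed = NULL) {
  gen <- function() {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# independent identity oracle: Biostrings global alignment with the same
# scoring; identity = matching columns / columns excluding terminal gap runs
bios_identity <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 10, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gap <- pa == "-" | pb == "-"
  keep <- seq_along(pa)
  while (length(keep) && gap[keep[1L]]) keep <- keep[-1L]
  while (length(keep) && gap[keep[length(keep)]]) keep <- keep[-length(keep)]
  sum(pa[keep] == pb[keep]) / length(keep)
}

bios_score <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                 baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 1))
}

# quality_reads with flat qualities
flat_reads <- function(seqs, q = 30L, sample = "s1",
                       id = sprintf("r%03d", seq_along(seqs))) {
  quality_reads(id, seqs, lapply(nchar(seqs), function(n) rep(q, n)),
                sample = sample)
}

# small shared mock fixture, built once per test run
.fixtures <- new.env(parent = emptyenv())

mock_fixture <- function() {
  if (is.null(.fixtures$mock)) {
    spec <- mock_spec(n_taxa = 8, length_range = c(400L, 500L), seed = 42)
    db <- generate_reference_set(spec)
    .fixtures$mock <- list(spec = spec, db = db)
  }
  .fixtures$mock
}
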