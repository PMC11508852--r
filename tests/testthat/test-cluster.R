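test_that("dereplication groups identical sequences and preserves counts", {
  reads <- quality_reads(
    sprintf("r%d", 1:4),
    c("AAA", "AAA", "AAA", "AAT"),
    rep(list(rep(30L, 3)), 4),
    sample = c("s1", "s1", "s1", "s2"))
  z <- dereplicate(reads)
  expect_identical(z$seq, c("AAA", "AAT"))
  expect_identical(z$size, c(3L, 1L))
  expect_identical(unclass(z$table)[1, ], c(s1 = 3L, s2 = 0L))
  expect_identical(unclass(z$table)[2, ], c(s1 = 0L, s2 = 1L))
  expect_identical(sum(z$size), length(reads))

  all_same <- flat_reads(rep("ACGTACGT", 5))
  expect_length(dereplicate(all_same)$size, 1L)

  distinct <- flat_reads(replicate(6, rand_seq(30)))
  expect_identical(dereplicate(distinct)$size, rep(1L, 6))
})

test_that("greedy clustering assigns by best match at the identity threshold", {
  A <- rand_seq(100, seed = 31)
  B <- mutate_positions(A, 10, seed = 32)            # 1 sub: 99% to A
  C <- mutate_positions(A, c(5, 25, 45, 65, 85), seed = 33)  # 5 subs: 95%
  reads <- flat_reads(c(rep(A, 10), rep(B, 2), C))
  z <- dereplicate(reads)
  cl <- greedy_cluster(z, cluster_params(0.98))
  expect_identical(nrow(cl$table), 2L)
  expect_setequal(as.integer(rowSums(cl$table)), c(12L, 1L))
  # membership contract, checked post hoc with the identity oracle
  for (lab in z$label) {
    otu <- cl$membership[[lab]]
    ident <- pairwise_identity(z$seq[match(lab, z$label)],
                               cl$centroids[[otu]])
    expect_gte(ident, if (z$seq[match(lab, z$label)] == cl$centroids[[otu]]) 1 else 0.98)
  }
  # each centroid was < t from all earlier centroids at creation
  cents <- cl$centroids
  if (length(cents) > 1L) {
    for (i in 2:length(cents)) {
      for (j in 1:(i - 1L)) {
        expect_lt(pairwise_identity(cents[[i]], cents[[j]]), 0.98)
      }
    }
  }
})

test_that("clustering at identity 1 reproduces dereplication", {
  reads <- flat_reads(replicate(8, rand_seq(60)))
  z <- dereplicate(reads)
  cl <- greedy_cluster(z, cluster_params(1.0))
  expect_identical(nrow(cl$table), length(z$size))
  expect_identical(sort(as.integer(rowSums(cl$table))), sort(z$size))
})

test_that("read counts are conserved through clustering", {
  fx <- mock_fixture()
  sim <- simulate_reads(fx$db, fx$spec, n_reads = 150, quality_targets = 20,
                        seed = 35)
  tr <- trim_and_orient(sim$reads)
  z <- dereplicate(tr$reads)
  cl <- greedy_cluster(z)
  expect_identical(sum(cl$table), sum(z$size))
  expect_identical(sum(cl$table), length(tr$reads))
})

test_that("chimeras between abundant parents are flagged; parents and near-copies are not", {
  A <- rand_seq(300, seed = 41)
  B <- rand_seq(300, seed = 42)
  chi <- paste0(substr(A, 1, 150), substr(B, 151, 300))
  reads <- flat_reads(c(rep(A, 10), rep(B, 8), chi))
  z <- dereplicate(reads)
  flags <- detect_chimeras(z, min_shared_kmers = 10L)
  expect_identical(flags, c(FALSE, FALSE, TRUE))

  # independent oracle: exhaustive breakpoint scan on raw strings
  split_at <- function(a, b, k) paste0(substr(a, 1, k), substr(b, k + 1, 300))
  best <- min(vapply(1:299, function(k) {
    ch <- strsplit(split_at(A, B, k), "")[[1L]]
    qs <- strsplit(chi, "")[[1L]]
    sum(ch != qs)
  }, numeric(1)))
  expect_identical(best, 0)

  # a read nearly identical to an abundant parent is not chimeric
  near <- mutate_positions(A, 7, seed = 43)
  z2 <- dereplicate(flat_reads(c(rep(A, 10), rep(B, 8), near)))
  expect_false(any(detect_chimeras(z2, min_shared_kmers = 10L)))

  # the most abundant zOTU is never flagged
  expect_false(detect_chimeras(z)[1L])
})

test_that("match lists contain exactly the pairs above the cutoff", {
  A <- rand_seq(200, seed = 51)
  B <- mutate_positions(A, sample(200, 10), seed = 52)  # ~95%
  C <- rand_seq(200, seed = 53)                          # unrelated
  cents <- c(OTU1 = A, OTU2 = B, OTU3 = C)
  ml <- build_match_list(cents, min_match = 84)
  expect_identical(nrow(ml), 2L)
  expect_setequal(ml$query, c("OTU1", "OTU2"))
  expect_true(all(ml$pident >= 84))
  expect_true(all(ml$query != ml$target))

  ident <- c(OTU1 = A, OTU2 = A)
  ml2 <- build_match_list(ident, min_match = 84)
  expect_identical(nrow(ml2), 2L)
  expect_true(all(ml2$pident == 100))

  far <- c(OTU1 = A, OTU3 = C)
  expect_identical(nrow(build_match_list(far, min_match = 84)), 0L)
})

test_that("LULU curation merges erroneous daughters and conserves counts", {
  A <- rand_seq(200, seed = 61)
  D <- mutate_positions(A, sample(200, 10), seed = 62)  # 95% daughter
  m <- matrix(c(100L, 120L, 10L, 12L), nrow = 2, byrow = TRUE,
              dimnames = list(c("P", "D"), c("s1", "s2")))
  tab <- unit_table(m, kind = "OTU")
  ml <- build_match_list(c(P = A, D = D), min_match = 84)
  cur <- lulu_curate(tab, ml)
  expect_identical(nrow(cur$table), 1L)
  expect_identical(as.integer(colSums(cur$table)), c(110L, 132L))
  expect_identical(cur$log$daughter, "D")
  expect_identical(cur$log$parent, "P")

  # daughter occupying a sample the parent lacks is kept
  m2 <- matrix(c(100L, 0L, 10L, 12L), nrow = 2, byrow = TRUE,
               dimnames = list(c("P", "D"), c("s1", "s2")))
  cur2 <- lulu_curate(unit_table(m2, kind = "OTU"), ml)
  expect_identical(nrow(cur2$table), 2L)

  # empty match list returns the table unchanged
  empty_ml <- data.frame(query = character(), target = character(),
                         pident = numeric())
  cur3 <- lulu_curate(tab, empty_ml)
  expect_equal(unclass(cur3$table), m, ignore_attr = TRUE)
})

test_that("unit tables drop all-zero rows and validate counts", {
  m <- matrix(c(0L, 0L, 3L, 1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- unit_table(m, kind = "zOTU")
  expect_identical(rownames(tab), "b")
  expect_error(unit_table(matrix(-1L, 1, 1, dimnames = list("a", "s1")),
                          kind = "OTU"), "non-negative")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_unit_table(tab, p)
  back <- read_unit_table(p, kind = "zOTU")
  expect_identical(unclass(back), unclass(tab))
})
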