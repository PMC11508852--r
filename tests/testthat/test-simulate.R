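test_that("reference sets honour taxon count, divergence and lineage format", {
  # two taxa, no near pairs: clearly divergent
  db2 <- generate_reference_set(mock_spec(n_taxa = 2, seed = 5))
  expect_length(db2$accession, 2L)
  expect_lt(pairwise_identity(db2$seq[1], db2$seq[2]), 0.9)

  # a near pair at 1.5% divergence
  dbp <- generate_reference_set(
    mock_spec(n_taxa = 3, near_pairs = list(c(0.015, 1)), seed = 6))
  L <- nchar(dbp$seq[1])
  expect_equal(pairwise_identity(dbp$seq[1], dbp$seq[3]),
               1 - round(0.015 * L) / L, tolerance = 1 / L)

  # single-reference spec is trivially valid
  db1 <- generate_reference_set(mock_spec(n_taxa = 1, seed = 7))
  expect_length(db1$accession, 1L)

  # 7-rank dummy lineage ending in an SH code
  lin <- dbp$lineage[[1L]]
  expect_identical(names(lin), c("d", "p", "c", "o", "f", "g", "s"))
  expect_match(lin[["s"]], "^SH[0-9]{7}\\.10FU$")
  # the near-pair partner shares the lineage through genus, not the SH
  expect_identical(dbp$lineage[[3L]][["g"]], dbp$lineage[[1L]][["g"]])
  expect_false(dbp$lineage[[3L]][["s"]] == dbp$lineage[[1L]][["s"]])
})

test_that("unreachable divergence raises an error", {
  expect_error(
    generate_reference_set(
      mock_spec(n_taxa = 2, length_range = c(50L, 50L),
                near_pairs = list(c(0.001, 1)), seed = 1)),
    "unreachable")
})

test_that("quality strings reach their target probability-domain mean", {
  q0 <- make_quality_string(20, 700, error_model(qual_spread = 0))
  expect_identical(q0, rep(20L, 700))
  expect_equal(mean_phred(q0), 20)

  q1 <- make_quality_string(15, 700, error_model(qual_spread = 3), seed = 8)
  expect_gte(mean_phred(q1), 14.5)
  expect_lte(mean_phred(q1), 15.5)
  expect_true(all(q1 >= 2 & q1 <= 50))

  expect_identical(make_quality_string(10, 1, error_model(qual_spread = 0)),
                   10L)
  expect_error(make_quality_string(60, 10), "target_mean_q")
})

test_that("high-quality reads copy their template almost exactly", {
  fx <- mock_fixture()
  db1 <- reference_db(fx$db$accession[1], fx$db$seq[1], fx$db$lineage[1])
  spec1 <- mock_spec(n_taxa = 1, length_range = c(400L, 500L), seed = 1)
  sim <- simulate_reads(db1, spec1, n_reads = 100, quality_targets = 40,
                        chimera_rate = 0, seed = 9)
  expect_length(sim$reads, 100L)
  expect_true(all(sim$truth$taxon == db1$accession[1]))
  # Q40 = 1e-4 per-base error: a handful of errors across ~45k bases
  expect_lte(sum(sim$truth$n_errors), 25L)
  expect_identical(nrow(sim$truth), length(sim$reads))
})

test_that("chimera_rate 1 makes every read a flagged two-parent chimera", {
  fx <- mock_fixture()
  db2 <- reference_db(fx$db$accession[1:2], fx$db$seq[1:2], fx$db$lineage[1:2])
  spec2 <- mock_spec(n_taxa = 2, length_range = c(400L, 500L), seed = 1)
  sim <- simulate_reads(db2, spec2, n_reads = 30, quality_targets = 30,
                        chimera_rate = 1, seed = 10)
  expect_true(all(sim$truth$is_chimera))
  expect_true(all(!is.na(sim$truth$parent_a) & !is.na(sim$truth$parent_b)))
  expect_true(all(sim$truth$parent_a != sim$truth$parent_b))
  # breakpoint restricted to the middle 80% of the amplicon
  lens <- nchar(fx$db$seq[match(sim$truth$parent_a, fx$db$accession)])
  expect_true(all(sim$truth$breakpoint >= 0.1 * lens - 1))
  expect_true(all(sim$truth$breakpoint <= 0.9 * lens + 1))
})

test_that("realized per-base error rate at Q10 is about 10%", {
  fx <- mock_fixture()
  spec <- fx$spec
  sim <- simulate_reads(fx$db, spec, n_reads = 40,
                        quality_targets = 10,
                        model = error_model(qual_spread = 0), seed = 11)
  total_bases <- sum(nchar(fx$db$seq[match(sim$truth$taxon,
                                           fx$db$accession)])) +
    length(sim$reads) * 42L  # primer flanks carry errors too
  expect_gt(total_bases, 1e4)
  rate <- sum(sim$truth$n_errors) / total_bases
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("error-free, chimera-free reads equal their template between primers", {
  fx <- mock_fixture()
  sim <- simulate_reads(fx$db, fx$spec, n_reads = 50, quality_targets = 50,
                        model = error_model(qual_spread = 0), seed = 12)
  # Q50 = 1e-5 error; with ~23k bases a clean draw is overwhelmingly likely
  clean <- sim$truth$n_errors == 0L
  tr <- trim_and_orient(sim$reads[which(clean)])
  expect_identical(tr$reads$seq,
                   fx$db$seq[match(sim$truth$taxon[clean], fx$db$accession)])
})

test_that("simulation is byte-identical under a fixed seed", {
  fx <- mock_fixture()
  s1 <- simulate_reads(fx$db, fx$spec, n_reads = 25, quality_targets = c(12, 25),
                       chimera_rate = 0.2, seed = 77)
  s2 <- simulate_reads(fx$db, fx$spec, n_reads = 25, quality_targets = c(12, 25),
                       chimera_rate = 0.2, seed = 77)
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$reads, p1)
  write_fastq(s2$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth, s2$truth)
})

test_that("ground truth round-trips through its TSV form", {
  fx <- mock_fixture()
  sim <- simulate_reads(fx$db, fx$spec, n_reads = 10, quality_targets = 20,
                        chimera_rate = 0.3, seed = 13)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, p)
  back <- read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(sim$truth))
  expect_identical(back$read_id, sim$truth$read_id)
  expect_identical(back$n_errors, sim$truth$n_errors)
})
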