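# nanoits

Nanopore-style full-length ITS metabarcoding in R, with a built-in
evaluation framework for choosing a minimum read-quality threshold.

## The problem

Long-read amplicon sequencing recovers the full fungal ITS barcode in one
read, but at per-base error rates where the usual quality-control question
— *which reads are good enough to keep?* — has no obvious answer. The
answer depends on how taxonomic units are defined:

* **98% OTUs** (greedy centroid clusters, radius `r = 0.02`) are inflated
  by sequencing error: two reads of one template with per-base error `e`
  lie about `2e` apart, so reads escape their own cluster once `e`
  approaches `r`. The Phred score at which the expected per-base error
  equals the radius is `Q = -10·log10(r)`, i.e. **Q17** for 98% OTUs;
  inflation only collapses several bins above it.
* **Species hypotheses (SHs)** are reference-based: reads are dereplicated
  into zero-radius OTUs (zOTUs), classified with a k-mer bootstrap
  (SINTAX-style) classifier against an SH-annotated reference, filtered on
  species-rank confidence (0.95 for singleton zOTUs, 0.8 for multitons),
  and aggregated per SH. Recovery is largely insensitive to read quality,
  so quality filtering can be replaced by *classifiability* filtering.

The package provides every stage as a plain R function: a mock-community
read simulator with ground truth (`generate_reference_set()`,
`simulate_reads()`), FASTQ I/O and primer reorientation/trimming,
probability-domain mean-Phred computation and quality stratification,
dereplication, greedy clustering at a fixed identity, de novo chimera
flagging, LULU-style curation, SINTAX-format reference handling and
classification, SH aggregation, and per-Phred recovery curves with a
windowed stabilization detector (`recovery_curve()`,
`detect_stabilization()`). `run_pipeline()` drives the whole thing from a
directory of per-sample FASTQ folders, and
`inst/scripts/nanoits-pipeline.R` exposes it on the command line with
`--id`, `--q`, `--sintax`, `--skip-lulu`, `--approach`, `--seed`.

## Worked example

Simulate a small mock community with one near-neighbour reference pair
(1.5% divergence, inside the 2% clustering radius), reads spread across
mean-Phred bins 14–26, and 2% chimeras; then compare the two unit
definitions:

```r
library(nanoits)
spec <- mock_spec(n_taxa = 8, length_range = c(400, 500),
                  near_pairs = list(c(0.015, 1)), seed = 1)
db   <- generate_reference_set(spec)
sim  <- simulate_reads(db, spec, n_reads = 1950,
                       quality_targets = 14:26, chimera_rate = 0.02,
                       seed = 2)
tr   <- trim_and_orient(sim$reads)

z  <- dereplicate(tr$reads)
z
#> <zotu_set> 1795 zOTU(s), 1945 read(s), 1787 singleton(s)
cl <- greedy_cluster(zotu_subset(z, !detect_chimeras(z)))
nrow(cl$table)
#> [1] 594
```

Almost every read is its own zOTU at these error rates, and pooling reads
from Q14 upward inflates 8 true taxa into 594 "98% OTUs" — the error-driven
inflation that a quality threshold must suppress. The SH approach on the
same reads, stratified by quality:

```r
rc <- recovery_curve(tr$reads, db = build_kmer_index(db),
                     params = eval_params(q_range = c(14L, 26L), depth = 100L,
                                          n_rep = 3L, approach = "SH",
                                          seed = 3))
summary(rc)
#>    q_bin mean_all sd_all mean_no_singletons sd_no_singletons
#> 1     14        8      0                  8                0
#> 2     15        8      0                  8                0
#> ...
#> 13    26        8      0                  8                0
detect_stabilization(rc)
#> [1] 14
```

All 8 mock taxa are recovered in every quality bin down to Q14: SH
recovery is already stable at the lowest bin, so the classifiability
filter substitutes for quality filtering. Running the same curve with
`approach = "OTU"` shows the opposite picture — counts fall steeply with
quality and stabilize only in the mid-twenties, several bins above the
Q17 radius equivalence.

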