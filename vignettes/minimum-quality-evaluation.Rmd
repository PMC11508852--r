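---
title: "Quality thresholds for long-read ITS metabarcoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality thresholds for long-read ITS metabarcoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoits)
```

## The problem

Nanopore sequencing reads the full-length fungal ITS region in a single
read, but with per-base error rates far above short-read platforms. The
standard quality-control instinct — discard reads below some mean Phred
score — interacts badly with the two ways metabarcoding pipelines define
taxonomic units:

* **98% OTUs** (greedy centroid clusters with a 2% radius) are inflated by
  sequencing error. Two reads of the same template, each carrying an error
  fraction `e`, sit roughly `2e` apart, so reads start escaping their own
  cluster once `e` approaches the radius. A Phred score `Q` corresponds to
  an expected per-base error `10^(-Q/10)`; the radius-equivalent score is
  `phred_for_radius(0.02) = 17`, and error-driven OTU inflation only
  collapses well above it.
* **Species hypotheses (SHs)** are reference-based: reads are dereplicated
  into zero-radius OTUs (zOTUs), classified against an SH-annotated
  reference database, filtered on classification confidence, and aggregated
  per SH. Because the unit is defined by the reference rather than by
  read-to-read distances, recovery is largely insensitive to read quality.

This package implements both unit definitions, a mock-community read
simulator with controlled quality, and an evaluation layer that asks: *at
which mean-Phred bin does taxonomic-unit recovery stabilize?*

## Mean read quality

"Average Phred score" is computed in probability domain:
`mean_phred(q) = -10 log10(mean(10^(-q_i/10)))`. The arithmetic mean of
Phred values always overstates quality (convexity of `10^(-q/10)`); the
probability-domain mean is the convention used by long-read quality
filters, and a read of all-Q10 bases has exactly 90% expected accuracy
under it. Reads are assigned to integer quality bins by rounding the mean
(round half up); the binning rule is a package convention — tools differ
and flooring would shift every bin boundary by half a unit without
changing any qualitative conclusion.

## The simulator and what it does (not) emulate

`generate_reference_set()` builds a mock community of `n_taxa` references
(default 16, matching a phylogenetically diverse ectomycorrhizal mock
community) as uniform-random nucleotide sequences of 650–780 bp around a
shared 150 bp conserved core. The core mimics the 5.8S region: it gives
cross-taxon chimeras and the k-mer classifier realistic shared signal, so
classification confidence and chimera formation are not artificially easy.
`near_pairs` entries create reference pairs at an exact substitution
divergence — e.g. `c(0.015, 1)` yields one pair at 98.5% identity, inside
the 2% clustering radius, emulating congeneric species pairs that 98% OTUs
cannot separate.

`simulate_reads()` copies a reference (or, with probability
`chimera_rate`, joins two references at a single breakpoint uniform in the
middle 80% of the amplicon), adds the forward/reverse primer flanks,
draws a per-base quality string at the read's target mean Phred
(`make_quality_string()`, bisection on the offset of a normal spread so the
probability-domain mean lands within 0.5 of target), and injects errors
per base at rate `10^(-q/10)` with class drawn from the error model.
Defaults are substitution:insertion:deletion = 0.5:0.25:0.25 and a 3-Phred
per-base spread — a plausible long-read profile, chosen once and exposed as
parameters, not fitted to any instrument. Half the reads are emitted
reverse-complemented so primer reorientation is exercised. A chimera
fraction of 0.02 is used in the package's own evaluations.

Deliberately not simulated: signal-level artefacts, homopolymer-specific
error enrichment, sequencing adapters (only primers are simulated; adapter
trimming is upstream of this toolkit), barcode hopping. Passing tests on
this simulator therefore demonstrate the pipeline's logic — conservation,
thresholds, stabilization behaviour — not instrument-specific base-caller
performance on real data.

## Identity, clustering and curation

Pairwise identity is matching columns over alignment columns of an
affine-gap global alignment (match +2, mismatch −4, gap open −10, gap
extend −1), with terminal gap runs excluded from the denominator. End gaps
are *scored* (the alignment is forced end to end) rather than free: with
free end gaps, two unrelated sequences can align a spurious 2–8 bp
dovetail of perfect matches and report identity 1.0, which would poison
match lists and centroid assignment. Excluding the terminal gap columns
from the denominator keeps length differences from being double-counted.

`greedy_cluster()` processes zOTUs in decreasing abundance and assigns each
to the *best-matching* existing centroid at or above the identity
threshold (ties: larger founding size, then lexicographic), else promotes
it to a new centroid. Best-match assignment is deterministic and
order-robust at this scale, unlike first-match. A conservative shared
k-mer screen skips centroids that cannot reach the threshold: `d` edits
destroy at most `k·d` of a sequence's k-mers, so any centroid with fewer
shared 8-mers than `|kmers(q)| − k·d_max` is below threshold with
certainty and is never aligned. The screen only ever skips provably
sub-threshold candidates, so best-match semantics are exact. Alignments in
the clustering loop run inside a diagonal band wide enough to contain every
alignment within the edit budget; identity of pairs far outside the budget
may be underestimated, which cannot affect a threshold decision.

Chimera flagging follows the classic two-parent model: a zOTU is chimeric
when two parents, each at least twice its abundance, explain it as a
single-crossover mosaic within `max_chimera_diffs = 1` differences, while
the nearest single parent alone is at least `min_div = 4` differences
away. Per-parent cumulative difference profiles over query positions make
the breakpoint scan a vector minimum. Two screens keep this cheap without
changing decisions: a parent whose shared k-mer count exceeds
`|kmers(q)| − k·min_div` is the only kind that can sit within `min_div`
differences (checked first; an almost-identical parent ends the scan), and
a query whose k-mers are not almost fully covered by the union of parent
k-mer sets cannot be assembled from two parents within the difference
budget. These parameter values are declared package conventions for the
abundance-skew chimera model, not values inferred from any dataset.

LULU-style curation uses the published defaults (minimum match 84%,
minimum ratio 1, co-occurrence 0.95): daughters are visited from least to
most abundant and merged into their best more-abundant parent that
co-occurs in at least 95% of the daughter's samples with at least the
required per-sample abundance ratio. Counts are conserved exactly; merges
are logged.

## Classification and the dual-threshold filter

The classifier is a k-mer bootstrap (SINTAX-style) procedure with the
published hyperparameters: 8-mers, 32 k-mers drawn with replacement per
bootstrap, 100 bootstraps, top hit per bootstrap by shared k-mer count
with seeded uniform tie-breaks. Per-rank confidence is the fraction of
bootstraps whose top hit carries the rank value; because every hit carries
a full lineage, confidences are non-increasing from domain to species by
construction. The classifiability filter applies to the species-rank
confidence (the rank at which SH codes live — the minimum across ranks
would be equivalent here, but species rank is the documented choice):
singleton zOTUs need 0.95, multiton zOTUs 0.8, reflecting that a unit
supported by two or more identical long reads is unlikely to be an error
artefact. Retained conspecific zOTUs are aggregated per SH. Reference
databases use the SINTAX FASTA header grammar
(`>ID;tax=d:...,p:...,s:SH0910702.10FU;`), with missing intermediate ranks
permitted, and dummy SH codes (`SH0000001.10FU` pattern) can be appended
for local reference sequences.

## The evaluation layer

`recovery_curve()` stratifies reads into integer mean-Phred bins, subsamples
each bin to a fixed depth (the highest-quality bin's read count, in the
original design), runs the chosen approach end to end, and records unit
counts with and without singleton units over replicates. Replicate seeds
derive from the master seed by fixed offsets and are recorded; all
variance comes from subsampling and seeded tie-breaks, and the per-bin
standard deviation is always reported.

`detect_stabilization()` formalizes "recovery stops changing": the smallest
bin `Q*` such that every consecutive-bin relative change within
`[Q*, Q* + window]` is at most `epsilon` (defaults: window 3, epsilon
0.05). Published analyses of this kind typically judge stabilization from
a loess-smoothed plot; the windowed rule is one defensible formalization
whose parameters are exposed, and the loess smoother in
`plot.recovery_curve()` is a visual aid only, never part of the decision.
On the curve `100, 80, 60, 50, 49, 49, 48, 48` over Q21–Q28 the rule
returns Q24.

## Problem sizes and numerical choices

The package's own evaluations run at desk scale, chosen once: 16 taxa,
1500 simulated reads per bin for Q18–Q28 and 1100 below, depth 1000 with
10 replicates for the OTU inflation curve, depth 400 with 4 replicates for
SH stability, and 100-replicate designs remain available through
`eval_params()`. Quality strings are clipped to Phred [2, 50]; inserted
bases inherit the read's target quality; subsampling is without
replacement; rejected reads always carry a reason code in the stage log.

## Known limitations

* The error model is i.i.d. per base given the quality string; real
  Nanopore errors cluster in homopolymers, so absolute OTU-inflation
  levels on real data will differ (the qualitative collapse above the
  radius-equivalent Phred score does not depend on this).
* The chimera detector only sees abundance-skewed, single-crossover
  chimeras, as its model states.
* Identity is one convention among several used by clustering tools;
  thresholds are not numerically transferable between conventions.
* The classifier shares the known compression of bootstrap confidence when
  references are locally dense; dummy-SH insertion of near-duplicate
  references lowers species confidence for their shared neighbourhood.
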