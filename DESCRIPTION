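Package: nanoits
Title: Nanopore Full-Length ITS Metabarcoding with Minimum-Quality Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for long-read (Nanopore-style) full-ITS
    amplicon metabarcoding. Provides a mock-community read simulator with
    quality-conditioned errors and chimeras, FASTQ preprocessing (primer
    reorientation and trimming, probability-domain mean Phred scores, quality
    stratification, seeded subsampling), dereplication into zOTUs, greedy
    centroid clustering at a fixed identity threshold, de novo chimera
    flagging, LULU-style post-clustering curation, a k-mer bootstrap (SINTAX
    style) taxonomy classifier over SINTAX-formatted references with a
    dual-threshold classifiability filter and species-hypothesis aggregation,
    and an evaluation framework that locates the Phred score at which
    taxonomic-unit recovery stabilizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
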