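Package: regionperm
Title: Permutation Tests for Genomic Region-Set Overlap Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Overlap statistics and genome-aware permutation tests for sets of
    genomic intervals (ATAC-seq or ChIP-seq peak sets in BED format).
    Implements count-once overlap counting, region randomization that
    preserves region lengths and (optionally) chromosome assignment while
    avoiding masked regions, the classical single-set permutation enrichment
    test summarized by a z-score and an add-one empirical p-value, a
    differential permutation test for the difference in overlap counts of two
    query sets against a common reference, and Yates-corrected chi-square
    colocalization comparisons.  A synthetic region-set generator with a
    planted enrichment fraction provides ground-truth fixtures for
    calibration and power experiments, and a YAML manifest runner
    orchestrates batches of tests into TSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
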