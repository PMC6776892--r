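Package: ezswitch
Title: Broad-Mark Island Calling and Expression-Concordant Polycomb
    Target Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for identifying genome-wide
    redistribution of a broad Polycomb chromatin mark between cellular
    states and distilling it into a short list of state-specific,
    expression-concordant target genes. Provides broad histone-mark
    island calling from fragment intervals, replicate consensus merging,
    an H3K27me3 co-occupancy filter, a Poisson differential-binding test
    with large-magnitude thresholds, strand-aware peak-to-TSS annotation
    with tie rules, a negative-binomial two-group differential-expression
    test with TPM filtering, genomic feature enrichment via Fisher's
    exact test, promoter-methylation and RNA-FISH scoring utilities, and
    a synthetic-data generator with planted, machine-readable ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, RNASeq, DifferentialExpression, PeakDetection,
    Epigenetics, GeneRegulation
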