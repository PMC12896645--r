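Package: retrovis
Title: Retroviral Integration-Site Resistance Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for retroviral insertional-mutagenesis
    resistance screens read out by integration-site sequencing (VIS-NGS).
    Provides error-tolerant LTR/linker adapter trimming, mapping-quality
    filtering, window-based collapsing of junction reads into viral
    integration-site (VIS) loci with reads-per-million normalisation and
    nearest-gene annotation, the replicate-concordance filtering cascade,
    Fisher exact detection-frequency and Student t read-depth enrichment
    tests, candidate-gene selection with verification-cohort
    categorisation, and a single-cell fraction-positive validation
    (CPM thresholding, chi-squared tests, Bonferroni correction).
    A synthetic-data module simulates clonal populations under
    fitness-driven drug selection with full ground truth, so the whole
    pipeline is testable end to end without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Matrix,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    S4Vectors,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
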