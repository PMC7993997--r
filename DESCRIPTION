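Package: riboflux
Title: Downstream Ribosome-Profiling Analysis of Ribosome Recycling Defects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for yeast ribosome-profiling studies of
    40S ribosome recycling and initiation competition. Implements
    stop-codon-anchored metagene profiles with queuing-peak detection,
    3'UTR-to-ORF footprint occupancy ratios, differential translational
    efficiency inference via a negative-binomial generalized linear model
    with an assay-by-condition interaction, an upstream open reading frame
    (uORF) translation-calling filter cascade with relative ribosome
    occupancy (RRO) statistics, mRNA-feature association analyses
    (Kozak-context scores, group tests, rank correlations, clustering),
    and a Lodish-style model of mRNAs competing for a limiting pool of
    43S preinitiation complexes. A seeded synthetic-data generator
    emulates the statistical structure of recycling-defect ribosome
    profiling data so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    MASS,
    tibble,
    readr,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
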