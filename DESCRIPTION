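Package: atacqc
Title: Quality Control and Digital Footprinting for ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control metrics and digital genomic footprinting for
    ATAC-seq experiments. Converts aligned paired-end fragments into
    offset-corrected Tn5 cut sites (+4/-5), computes the TSS enrichment
    score, the Percent Reference peak Coverage (PRC) metric with its
    multi-sample reference-peak calibration, replicate-concordance hotspot
    filtering, genomic-distribution annotation, fragment-size nucleosome
    phasing, PWM motif scanning with exact p-value thresholds, and a
    hexamer-bias-corrected footprint depth statistic with k-mer
    mappability masking. Includes a synthetic-data generator that plants
    TSS enrichment, insertion bias, footprints and replicate peak sets
    with known truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
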