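Package: heatsnp
Title: Pooled-Transcriptome SNP Classification and Heat-Tolerance
    Candidate-Gene Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline from pooled-transcriptome variant calls to
    heat-tolerance candidate SNPs in diverged subspecies pools: post-call
    quality and density filtering, cross-population SNP classification
    against a unigene reference, allelic-imbalance scoring from pooled
    read depths, HRM-assay feasibility screening of candidate-gene SNPs,
    accumulated degree-hour heat phenotyping with extreme-group sampling,
    QC'd allelic case-control association (exact Hardy-Weinberg and
    two-sided Fisher tests), RPKM-based two-library differential
    expression, and allele-specific qPCR delta-delta-CT quantification
    with primer-efficiency normalization. A synthetic-data generator with
    known ground truth replaces raw sequencing reads for testing and
    simulation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
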