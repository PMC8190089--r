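Package: heatmem
Title: Stochastic Nucleosome-State Modelling of Heat-Stress Transcriptional Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models histone-modification-based transcriptional memory of heat
    stress at Arabidopsis heat-shock-protein loci. A locus of N nucleosomes,
    each repressively modified (H3K27me3), unmodified, or actively marked
    (H3K4me3), evolves under recruited conversions plus temperature-driven
    JMJ-demethylase, heat-shock-factor, and damage signals, with an mRNA
    output. Provides a deterministic mean-field engine, an exact stochastic
    simulation algorithm with time-varying rates, a small-system master
    equation oracle, joint fitting of wild-type and demethylase-mutant time
    courses, acclimation-memory scans over nucleosome number, a memory-gene
    screening pipeline on count data (negative-binomial likelihood-ratio
    tests, FDR screening, profile clustering, hypergeometric overlap,
    fold-enrichment region calls), and synthetic-data generators with known
    ground truth for temperature series, assay time courses, and count
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    lhs,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
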