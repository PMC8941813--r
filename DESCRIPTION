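Package: surfscore
Title: Multi-Omic Surfaceome Target Prioritization
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to nominate cell-surface antibody-drug-conjugate (ADC)
    targets from tumor-versus-normal transcriptomics and cell-line surface
    proteomics. Implements quantile normalization and Tukey median-polish
    summarization for microarray-style log-intensity matrices, ordinary and
    empirical-Bayes moderated two-group t-statistics with
    Benjamini-Hochberg adjustment, surfaceome-catalog filtering of
    upregulated genes, assembly of a multi-channel evidence matrix
    (genomic datasets plus cell-line-by-method proteomic runs), an additive
    evidence score with a dual genomic-and-proteomic prerequisite, Venn
    region counting, and small downstream statistics (Pearson correlation
    with a t-based p-value, caliper tumor volume, percent-of-control
    viability). A seeded synthetic-data generator produces expression
    cohorts with planted upregulated surface genes, proteomic presence
    lists with abundance-dependent detection, and a surfaceome catalog
    with ground truth, so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
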