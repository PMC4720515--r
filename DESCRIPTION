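Package: txdrift
Title: Transcriptional Drift and Drift-Variance Analysis for Aging Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies age-associated loss of co-expression in bulk transcriptomes
    through per-gene transcriptional drift (log fold-change against a young-adult
    reference) and group-level drift-variance, compares drift dispersion between
    conditions with a robust (trimmed-mean Brown-Forsythe) Levene test, classifies
    per-gene attenuation of drift under treatment with exact binomial tests, and
    models lifespan cohorts with Gompertz hazards, Mantel-Haenszel log-rank
    comparisons and Monte-Carlo power-of-detection. Ships a synthetic-data module
    generating aging RNA-seq count matrices and lifespan cohorts with known ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    flexsurv,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
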