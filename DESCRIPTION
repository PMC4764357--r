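Package: amplicon8p
Title: Simulation and Analysis of Broad Chromosome 8p11-12 Amplicons in
    Squamous Lung Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse tumour cohorts carrying a broad,
    heterogeneous chromosome 8p11-12 amplicon around FGFR1. Provides a seeded
    cohort simulator with ground truth (amplicon architectures, copy-number
    coupled expression, nanoString-style counts, quadruplicate qPCR Ct values,
    50-nucleus FISH spot counts and two-channel aCGH probe ratios), a count
    normalization chain with limit-of-detection flags, FGFR1 amplification
    callers from FISH ratios and delta-delta-Ct copy numbers, array-CGH
    baseline adjustment with circular binary segmentation and per-gene copy
    number summaries, and cohort statistics (pooled t-tests with Storey
    q-values, Spearman copy-number-expression correlation, replicate
    concordance, heatmap matrix export) orchestrated by a reproducible
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
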