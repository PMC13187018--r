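Package: trialomics
Title: Exact Single-Arm Trial Statistics and Survival-Quartile Genomic
    Signatures for Precision-Oncology Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the translational analysis of single-arm phase II
    oncology trials with paired genomic and transcriptomic profiling.
    Implements the A'Hern exact one-stage design and Clopper-Pearson
    confidence limits for response endpoints; Kaplan-Meier estimation and
    the two-sided log-rank (Mantel-Cox) test for stratified
    progression-free survival; derivation of resistance and sensitivity
    mutated-gene signatures from the extreme progression-free-survival
    quartiles of a microsatellite-stable subcohort, with carrier
    classification and held-out-quartile evaluation; tumor mutational
    burden and pathway stratification; count filtering, TMM
    normalization, principal components, and fold-change plus t-test
    differential expression; nearest-template-prediction molecular
    subtyping with a permutation false-discovery rate; hypergeometric
    over-representation analysis with Benjamini-Hochberg adjustment; and
    a seeded synthetic-cohort generator so every stage is testable
    without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    edgeR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
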