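Package: triowa
Title: Triangulated Outcome-Wide Association Analysis with Polygenic
    Scores and E-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for outcome-wide association studies of a count-coded
    exposure, triangulated against a polygenic-score analysis of the same
    outcome catalog. Provides a synthetic cohort generator with known
    ground truth (liability-threshold exposure items, LD-structured
    genotypes, emulated GWAS summary statistics), multiple imputation by
    chained equations with predictive mean matching and Rubin's-rules
    pooling, family-dispatched outcome regressions (linear, logistic,
    modified Poisson with robust variance, multinomial) with
    Benjamini-Hochberg false discovery rate control, point and
    confidence-limit E-values with benchmark-based robustness
    classification, clumping-and-thresholding polygenic score
    construction, principal-component genetic covariates, and a
    concordance classifier that summarizes agreement between the
    observational and genetic arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
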