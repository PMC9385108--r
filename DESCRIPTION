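Package: survmdr
Title: Multifactor Dimensionality Reduction for Censored Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single-locus and multi-locus (epistatic) SNP effects on
    right-censored survival and dichotomized outcomes with multifactor
    dimensionality reduction (MDR). Implements covariate-adjusted residual
    scoring (Cox martingale residuals and logistic score residuals),
    exhaustive 1- to 3-way high/low-risk genotype-cell classification,
    5-fold cross-validated model search under testing-balanced-accuracy and
    cross-validation-consistency selection strategies, repeated-run consensus
    models, permutation significance testing, iterative removal of
    main-effect SNPs together with their linkage-disequilibrium partners,
    and Cox/logistic regression plus Kaplan-Meier validation of the selected
    risk groupings. Includes genotype quality control (minor allele
    frequency, exact Hardy-Weinberg test, missingness, duplicate-marker
    pruning), a synthetic cohort generator with planted interaction effects
    for method evaluation, and readers/writers for PLINK .raw dosage files
    and phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
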