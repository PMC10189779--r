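Package: mrchain
Title: Two-Sample Mendelian Randomization with Multivariable and Mediation Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: allele harmonization across phenotype panels,
    instrument selection with linkage-disequilibrium clumping and
    instrument-strength metrics (variance explained and F statistics),
    univariable causal estimators (Wald ratio, inverse-variance weighted,
    MR-Egger, weighted median, contamination mixture), heterogeneity and
    pleiotropy diagnostics (Cochran's Q, Egger intercept, MR-PRESSO),
    multivariable MR, and mediation (network) MR with delta-method
    standard errors for the proportion mediated. A synthetic summary-statistic
    generator with known causal structure supports end-to-end validation,
    and a study driver chains the univariable screen, multivariable
    classification, and mediation stages with Bonferroni gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
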