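Package: mrtwosample
Title: Two-Sample Mendelian Randomization with Mediation and Multivariable
    Analyses from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics: instrument selection with a p-value
    relaxation ladder and greedy LD clumping, allele harmonization with
    palindromic-SNP handling, five univariable causal estimators (inverse
    variance weighted, MR-Egger, weighted median, simple and weighted mode),
    heterogeneity and pleiotropy diagnostics (Cochran's Q, Egger intercept,
    leave-one-out), multivariable MR via weighted multiple regression, and
    two-step mediation MR with the product-of-coefficients effect
    decomposition. A seeded generator of synthetic two-sample summary
    statistics (and exposure-mediator-outcome chains) with known truth
    supports calibration and recovery testing without external GWAS
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
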