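Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Analysis for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) and two-step mediation
    analysis from GWAS summary statistics. Provides allele harmonization and
    genomic-control adjustment for summary-statistic sets, instrument selection
    (significance, minor-allele-frequency, cis-window and F-statistic filters)
    with greedy LD clumping, six causal-effect estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, simple and weighted
    mode), a sensitivity suite (Cochran's Q, Egger intercept, MR-PRESSO,
    leave-one-out, Steiger directionality, power), product-of-coefficients
    mediation with delta-method confidence intervals and false-discovery-rate
    screening, and a seeded synthetic summary-statistics generator with known
    causal truth for calibration and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
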