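Package: cismr
Title: Drug-Target Cis-Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization from GWAS summary
    statistics. Covers cis-pQTL instrument selection (gene-region window
    filtering, LD clumping, coding-consequence exclusion, Cragg-Donald and
    conditional F statistics), allele harmonization across two-sample
    datasets, univariable and pleiotropy-robust causal estimators
    (inverse-variance weighted with multiplicative random effects,
    LD-matrix-adjusted IVW, MR-Egger, weighted median, contamination
    mixture, MR-PRESSO) and multivariable IVW. Implements two-step cis-MR
    mediation with the product and difference of coefficients decomposition
    and parametric bootstrap confidence intervals, plus a summary-statistic
    simulator with known causal and mediation structure for calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
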