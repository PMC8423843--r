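Package: mrpath
Title: Two-Sample Mendelian Randomization Along Causal Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Summary-statistics causal inference for chains of traits:
    harmonization of GWAS summary statistics, instrument selection by greedy
    LD clumping, the univariable estimator battery (inverse-variance weighted,
    MR-Egger with intercept test, I2GX and SIMEX correction, weighted median,
    weighted mode), radial-MR outlier removal by per-variant Cochran's Q,
    multivariable MR for direct effects, mediation analysis by the product of
    coefficients with delta-method standard errors, and cross-trait genetic
    correlation by LD-score regression with block-jackknife uncertainty.
    Includes a generator of two-sample GWAS summary statistics, mediation
    systems and LD-score panels with known ground truth, so every estimator
    can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
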