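Package: mrmediate
Title: Two-Sample Mendelian Randomization with Multivariable and Mediation
    Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A summary-statistics Mendelian randomization (MR) toolkit:
    instrument selection with p-value thresholding, LD clumping, allele
    harmonization and F-statistic strength filtering; five two-sample MR
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode); sensitivity diagnostics (Cochran's Q, Egger
    intercept, MR-PRESSO global/outlier/distortion tests, leave-one-out);
    multivariable MR with mutual adjustment; product-of-coefficients
    mediation decomposition with the proportion mediated; and a seeded
    generator of exposure/mediator/outcome GWAS summary-statistic triplets
    with known ground truth for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
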