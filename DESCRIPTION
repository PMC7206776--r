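Package: lifestyleMR
Title: Two-Sample Mendelian Randomization of Lifestyle Exposures on
    Cardiovascular Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: ingestion of instrument tables with configurable column
    mappings, allele harmonization across exposure and outcome datasets
    (strand flips, sign flips, palindromic ambiguity), causal estimation by
    fixed-effect inverse-variance weighting, simple and weighted median, and
    MR-Egger regression with its pleiotropy intercept test, Cochran's Q and
    I-squared heterogeneity diagnostics, and Bonferroni-aware reporting over
    an exposure-by-outcome grid. Ships instrument sets for
    moderate-to-vigorous physical activity, vigorous physical activity,
    sedentary behaviours and sleep duration as a packaged fixture, and a
    synthetic two-sample summary-statistics generator with known causal
    structure for calibration and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    readr,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
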