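Package: mrceliac
Title: Two-Sample Mendelian Randomization of Celiac Disease and Lymphoma Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument construction, harmonization and causal estimation for
    two-sample Mendelian randomization (2SMR) studies of celiac disease as a
    risk factor for lymphoma subtypes and small bowel cancer. Implements the
    Wald ratio, random-effects inverse-variance-weighted (IVW), MR-Egger and
    weighted-median estimators, the MR-PRESSO simulation-based pleiotropy and
    outlier test, multivariable MR, Cochran's Q heterogeneity and instrument
    strength diagnostics, Benjamini-Hochberg FDR correction and binary-outcome
    power calculation. Ships the instrument-level summary associations of the
    celiac disease to lymphoma study it reproduces (11 non-HLA instruments
    against 8 outcomes) as a plain-text fixture, plus a seeded generator of
    synthetic two-sample GWAS summary statistics with known causal truth for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
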