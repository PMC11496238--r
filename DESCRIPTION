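Package: triomr
Title: Two-Sample and Trio Mendelian Randomization with a Synthetic
    Trio-Cohort Generator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (inverse-variance
    weighted, MR-Egger, weighted median, weighted mode estimators with
    Cochran's Q, F-statistic, I2GX, SIMEX, Steiger-filtering and
    leave-one-out diagnostics), GWAS summary-statistic harmonization and
    LD clumping, polygenic score construction, and mother-father-child
    trio-MR regressions with a paternal negative control. Includes a
    seeded synthetic trio-cohort and summary-statistic generator with
    configurable causal structure (maternal intrauterine effects,
    child direct genetic effects, dynastic paths, directional
    pleiotropy, assortative mating and reverse causation) so that every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
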