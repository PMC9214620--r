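Package: medwas
Title: Medication-Wide Association Screening for Multiple-Birth Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for medication-wide association studies
    (MWAS) of preconception and periconception prescription exposure and
    multiple-birth outcomes in electronic health record (EHR) delivery
    cohorts. Provides a synthetic EHR cohort generator with planted
    effects, delivery-anchored exposure windowing and diagnosis-lookback
    covariate construction, per-medication logistic screening under three
    adjustment models with Bonferroni family-wise control, and
    confusion-matrix validation of significance calls against a
    fertility-medication gold standard.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
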