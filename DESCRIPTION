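Package: fiquant
Title: Quantitative Fluorescence-Intensity Staging of Oral Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of green-channel fluorescence
    intensity (G-values) in autofluorescence images of oral mucosa, built
    around a reproducible rat tongue carcinogenesis staging model
    (Control, low-grade dysplasia, high-grade dysplasia/carcinoma in situ,
    cancer). Provides a seeded synthetic fluorescence-image generator
    calibrated per histological stage, image loading and measurement-line
    profile extraction, per-sample and per-group intensity statistics,
    inclination-line (apex-to-root gradient) fitting, ROC-based stage
    discrimination with Youden cutoffs, one-way ANOVA and Monte-Carlo
    Dunnett many-to-one comparisons, and an end-to-end reproducible
    pipeline that emits the study-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    multcomp
Config/testthat/edition: 3
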