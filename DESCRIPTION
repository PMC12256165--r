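Package: patchfx
Title: Intrinsic Electrophysiology Feature Extraction and Group Statistics
    for Whole-Cell Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts passive membrane properties, single action-potential
    waveform features, spike-train adaptation statistics, medium
    afterhyperpolarisation and sag-index measures from current- and
    voltage-clamp sweep sets, applies series-resistance quality control, and
    compares experimental groups with a normality-gated statistical ladder
    (D'Agostino-Pearson / Shapiro-Wilk screening, variance-explained normal
    fit, standard transforms, rank-based two-way ANOVA, Fisher exact
    batteries).  Includes relative qPCR quantification by the 2^(-ddCt)
    method and a synthetic protocol generator with exact ground-truth
    ledgers for validating every extracted feature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    emmeans
Config/testthat/edition: 3
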