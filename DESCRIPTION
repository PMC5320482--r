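Package: chemvalid
Title: Chemometric Optimization and Validation of Multi-Residue
    Quantification Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the chemometric development and validation of
    multi-residue quantification methods such as QuEChERS LC-MS/MS
    pesticide assays. Covers two-level Plackett-Burman screening designs
    with pure-error t-tests of main effects, rotatable central composite
    designs with full second-order response-surface fits and lack-of-fit
    ANOVA, Derringer desirability multi-response optimization, analytical
    method validation (calibration linearity, matrix effects from slope
    ratios, dilution assessment, spike recovery and precision, limits of
    quantification, identification points, residue surveys), and bottom-up
    measurement-uncertainty budgets with root-sum-square combination and
    k = 2 expansion. A synthetic-data generator emulates the latent
    recovery surfaces, matrix-dependent calibration distortion, recovery
    variance components and low-prevalence contamination surveys that the
    workflow assumes, so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
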