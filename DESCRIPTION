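Package: mitoflux
Title: Quantification of Mitochondrial Bioenergetics Assays and Colitis
    Disease Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial function assays from raw
    instrument traces: oxygen fluxes and respiratory control ratios from
    high-resolution respirometry, Amplex-Red-calibrated hydrogen peroxide
    and superoxide production rates with the percent-electron-leak
    statistic, extinction-coefficient (Beer-Lambert) enzyme kinetics for
    electron transport chain complexes and citrate synthase with
    background subtraction and normalization to mitochondrial content.
    Includes a composite disease-activity index for rodent colitis
    models, colon morphometric ratios, group-comparison statistics
    (Student's t, one-way ANOVA with Tukey post-hoc, significance
    stars), a synthetic-data generator that emulates the assay traces
    and sex-by-treatment cohort structure for end-to-end testing, and a
    config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
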