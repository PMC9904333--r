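Package: normsupp
Title: Simulation and Analysis of Orientation-Tuned Contrast Surround Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying orientation-tuned contrast surround suppression
    with a divisive normalization observer model. Simulates cohorts of observers
    performing a two-alternative forced-choice contrast-matching task driven by
    Psi adaptive staircases (grid posterior over psychometric threshold and
    slope, expected-entropy stimulus placement), extracts per-condition
    perceived-contrast decrements with quality-control and outlier rules, fits
    an exponential orientation-tuning model (magnitude, tuning width, untuned
    offset) by separable nonlinear least squares, and provides group-level
    inference: mixed-design repeated-measures ANCOVA with Huynh-Feldt
    correction, one-way ANCOVAs on fit parameters, an acuity moderation test,
    and Benjamini-Hochberg corrected pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    car
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
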