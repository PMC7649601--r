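Package: braceroot
Title: Brace Root Contribution to Maize Anchorage from Force-Deflection Field Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-destructive field phenotyping of maize anchorage
    with hinged-footplate force-rotation devices. Converts force-rotation
    traces to force-deflection curves, segments loading cycles, and extracts
    the force-deflection slope by three methods (full-trace least squares,
    loading-cycles-only least squares, and per-cycle RANSAC). Quantifies the
    brace-root contribution to anchorage from sequential whorl-removal series
    (contribution ratio, difference, per-whorl ratios, and a cantilever
    beam-length correction), and provides the accompanying statistical layer:
    one- and two-way ANOVA with Tukey HSD, Pearson correlation, Tukey
    ladder-of-powers normalization, variance-components repeatability with
    parametric bootstrap, and two-predictor regression. A synthetic field
    generator simulates cantilever plants with per-whorl anchorage factors,
    loading-unloading hysteresis, sensor and wind noise, and plant-level
    random effects, so every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
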