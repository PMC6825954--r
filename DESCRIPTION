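Package: silgait
Title: Silhouette-Length Scaling for Markerless Rodent Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes rodent body-silhouette length and area from walkway
    video frames of a markerless gait-analysis system (background
    subtraction, tail removal by morphological opening with a diamond
    structuring element, hole filling, largest-object retention), scales
    gait parameters by body-size factors (silhouette length, dimensionless
    Froude-style speed, silhouette area, body weight, age), and evaluates
    scaling quality with Pearson correlations, repeated-measures and mixed
    ANOVA with lower-bound sphericity adjustment, Bonferroni post hoc
    tests and signed-significance heat-map tables. Includes a synthetic
    renderer and cohort simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
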