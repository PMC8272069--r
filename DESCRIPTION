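Package: vitifit
Title: Phenotyping of Overlapped Grape Berries by Edge Detection and
    RANSAC Ellipse Fitting
Version: 0.1.0
Authors@R:
    person("Vitifit", "Developers", email = "vitifit@example.org",
           role = c("aut", "cre"))
Description: Two-step phenotypic measurement of overlapped grape berries
    from images. Step one produces a per-pixel edge-probability map, either
    with a holistically-nested edge detection (HED) style convolutional
    network with dense side outputs and image-pyramid fusion, or with a
    classical gradient-magnitude fallback detector. Step two extracts
    contour pixels inside detector-supplied candidate boxes by connected
    region growing and fits an ellipse per box with an iterative
    (RANSAC-style) least-squares procedure, yielding per-berry long axis
    and projected area. Includes class-imbalance aware edge losses
    (weighted cross-entropy, Dice, and their convex combination), an
    evaluation suite (tolerance-matched Dice/recall/redundancy, ODS/OIS
    F-measures, non-maximum suppression thinning, fitting recall, average
    absolute relative deviation), and a synthetic scene generator that
    renders clusters of overlapping ellipses with occlusion, contour
    dropout and spurious edge noise so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
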