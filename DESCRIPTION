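Package: depthdensity
Title: Depth-Density Refinement of Semantic Segmentation for Depth Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for refining coarse semantic-segmentation masks of depth
    (time-of-flight) images via a per-pixel "depth density" score computed
    from local Gaussian statistics in a sliding window. Includes the original
    and distance-weighted variants of the operator, threshold-based mask
    refinement, the four standard segmentation metrics (pixel accuracy, mean
    accuracy, mean IoU, frequency-weighted IoU), valid-mode bilinear and
    full-mode de-convolution up-sampling operators, a seeded synthetic
    depth-scene generator for testing, 16-bit depth PNG and label-mask I/O,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
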