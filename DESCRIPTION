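Package: histonorm
Title: Reference-Free Brightness and Contrast Normalization for Serial-Section Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential histogram fitting for stacks of serial histologic
    section micrographs. Per-image gray-value histograms are summarized by
    landmarks (dynamic-range endpoints plus cumulative-frequency quantiles),
    landmark trajectories are smoothed across the stack by low-order
    polynomial fits, and each image is warped by a piecewise-linear
    gray-value transform onto its fitted target histogram. This compensates
    irregular staining-driven brightness and contrast variation without a
    reference image, so virtual reslices of the reconstructed volume are
    free of stripes. Includes classic histogram equalization and
    reference-based histogram specification as comparison baselines,
    Kullback-Leibler divergence and contrast-per-pixel evaluation metrics,
    a synthetic serial-section stack generator with known ground truth, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    optparse,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
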