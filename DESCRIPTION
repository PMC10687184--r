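Package: minor
Title: Mixed Gaussian and Impulsive Noise Reduction for Color Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust non-local-means denoising of 8-bit RGB images corrupted by
    mixed Gaussian and random-valued impulsive noise. Implements a trimmed,
    order-statistic patch dissimilarity that is insensitive to impulsive
    outliers, the MINOR filter built on it (global and standard blockwise
    aggregation), classic bilateral and non-local-means baselines, a mixed-noise
    simulator with a known impulse mask, synthetic phantom generators (flat,
    edges, gradients, disks, microarray-style spot grids), and restoration
    quality metrics (PSNR, MAE, multi-scale SSIM on a log scale, and an impulse
    removal index). Includes a small command-line interface for denoising
    images from the shell.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    withr,
    jsonlite,
    optparse,
    yaml,
    stats,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
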