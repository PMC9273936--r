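Package: wtmm2d
Title: Two-Dimensional Wavelet Transform Modulus Maxima Multifractal
    Analysis with Saturation Rescue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multifractal analysis of rough grayscale surfaces with the
    two-dimensional wavelet transform modulus maxima (WTMM) method:
    continuous wavelet transforms with first-order Gaussian-derivative
    wavelets, maxima chains and the space-scale skeleton of maxima lines,
    partition functions and canonical-ensemble estimates of the tau(q),
    h(q), D(q) and D(h) spectra.  Includes a fractional Brownian surface
    simulator with controlled saturation injection and a skeleton-pruning
    rescue procedure (modulus filter plus adjusted-slope filter) that
    removes the extraneous maxima lines created by flat saturated regions,
    restoring valid multifractal statistics on images with up to 20
    percent saturated pixels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ggplot2,
    rlang,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
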