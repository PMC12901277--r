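Package: radialpft
Title: Polar Fourier Transform Reconstruction for Radially Acquired MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Direct polar-coordinate reconstruction of 2D radially acquired
    MRI k-space via the Polar Fourier Transform: center-out reorganization of
    spokes, azimuthal FFT, order-n Hankel transforms built on a recursive
    integer-order Bessel evaluator with per-protocol kernel caching, i^n
    phasing, angular zero-padding, and nearest-neighbor polar-to-Cartesian
    conversion. Includes a standard Kaiser-Bessel gridding reconstructor as a
    comparator, analytic point-source and disk phantom simulators with noise,
    repetition and gradient-delay corruption, and pixel-wise SNR/CNR and
    point-spread-function metrics for characterizing behavior under angular
    undersampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    png,
    rhdf5,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
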