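Package: sorsdepth
Title: Depth Sensing Analysis for Spatially-Offset Raman Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate sampling depth in spatially-offset Raman
    spectroscopy (SORS) of layered turbid media. Provides a Monte Carlo
    bilayer-phantom simulator producing hyperspectral SORS cubes with known
    ground truth, a spectral preprocessing chain (channel truncation, cosmic
    ray removal, spectrometer smile correction, wavenumber calibration,
    system-response correction, bubble baseline removal, standard normal
    variate normalization), spectral angle mapper (SAM) curves against
    reference signatures, crossover-offset detection, and power-law
    depth-versus-offset model fitting with forward and inverse prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff,
    pracma,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
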