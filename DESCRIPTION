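Package: cardioflow
Title: Contraction Velocity and Calcium Transient Kinetics from
    Cardiomyocyte Fluorescence Video
Version: 0.1.0
Authors@R:
    person("cardioflow", "developers", email = "cardioflow@example.org",
           role = c("aut", "cre"))
Description: Quantifies the contraction and relaxation velocity of beating
    cardiomyocytes from fluorescence microscopy video using dense
    Horn-Schunck optical flow, and extracts calcium transient kinetics
    (time-to-peak, T90, maximal upstroke slope) and frame-difference
    calcium spark statistics from green-channel intensity.  Includes a
    synthetic video generator with exact ground truth for validating every
    analysis stage, readers and writers for multi-page TIFF and
    uncompressed AVI, event pairing of contraction/relaxation velocity
    peaks, group normalization to control = 100 percent, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
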