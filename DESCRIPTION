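Package: flimfret
Title: FRET-FLIM Analysis of TCSPC Photon Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of Forster resonance energy transfer (FRET) measured by
    fluorescence lifetime imaging microscopy (FLIM) with time-correlated single
    photon counting (TCSPC). Simulates photon-arrival decay histograms and
    per-pixel image cubes for cells with spatially structured FRET, fits
    instrument-response-convolved mono-exponential and fixed-lifetime
    bi-exponential decay models by Poisson maximum likelihood or
    Levenberg-Marquardt least squares, estimates the FRET percentage from
    amplitude fractions, computes phasor-plot coordinates with reference-dye
    calibration, builds pixel-wise lifetime maps with circular binning and
    intensity thresholding, and provides the cell-level statistics used to
    localize donor quenching (periphery versus interior paired lifetimes,
    regressions on acceptor expression, group comparisons, Pearson
    colocalization). Includes a minimal PicoQuant PT3 T3-mode photon-record
    codec and lossless TIFF/CSV container I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    withr,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
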