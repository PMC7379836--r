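Package: metroidr
Title: Denoising of Subcellular Fluorescence Signals by Equal-Area ROI
    Segmentation and Blind Source Separation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the METROID workflow for extracting low
    signal-to-noise transmembrane-potential events from fluorescence
    image stacks: morphological equal-area standardized segmentation
    (MESS) of a cell mask into inner and outer regions of interest,
    photobleaching removal by non-linear exponential curve fitting
    (SBPC/DBPC/FDPC input-window schemes), denoising of ROI time courses
    by blind source separation (PCA or FastICA, optionally followed by
    wavelet hard-threshold filtering of the selected source), and linear
    calibration of fluorescence to membrane potential.  Also provides
    the synthetic generators used to validate every stage: action
    potential and electroporation step surrogates, zero-mean Poisson
    shot noise, and full artificial fluorescence videos with basal
    fluorescence, per-ROI SNR gains, double-exponential photobleaching
    and per-pixel shot noise, including the prolate-spheroid induced
    membrane-potential field of Klee and Plonsey (1976).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
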