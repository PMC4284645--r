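Package: clampdyn
Title: Sliding-Clamp Loading and Unloading Dynamics from Live-Cell Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the dynamics of the bacterial beta2 sliding clamp from
    single-cell fluorescence microscopy. Implements a birth-death model of clamp
    loading and unloading with fixed-step and event-driven stochastic samplers and
    closed-form mean solutions; a synthetic mother-machine microscopy generator
    with exact ground truth (growth channels, replication-cycle focal dynamics,
    uneven illumination, stage drift, photobleaching, Poisson and read noise);
    a time-lapse quantification pipeline (rolling-ball background subtraction,
    flat-field correction, fiducial drift correction, kymographs, cell-cycle
    segmentation and background/cytoplasm/foci decomposition); single-fluorophore
    intensity calibration with photobleaching correction and dimer accounting;
    and PALM dwell-time analysis (a-trous wavelet spot detection, single-step
    trace filtering, censored-exponential fitting, bleach-rate correction and
    bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
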