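Package: photoblueR
Title: Quantifying Photoconversion Artifacts in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification of photoconversion (photoblueing)
    artifacts in confocal and STED microscopy. Provides seeded synthetic
    generators for first-order photoconversion kinetics, binned emission
    spectra, fluorescence correlation spectroscopy (FCS) intensity traces
    from two-dimensional Brownian diffusers with triplet blinking,
    two-channel ratiometric membrane image stacks, and TCSPC lifetime
    decays, together with the matching analyses: asymmetric log-normal
    spectral unmixing, multi-tau autocorrelation and FCS model fitting
    (molecule number, diffusion time, triplet fraction, molecular
    brightness, STED spot-size calibration), generalized-polarization (GP)
    ratiometric imaging, and mono-exponential lifetime estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
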