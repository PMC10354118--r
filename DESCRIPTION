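Package: mipqpi
Title: Simulation and Analysis of Wide-Field Mid-Infrared Photothermal
    Quantitative Phase Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing wide-field mid-infrared
    photothermal (MIP) quantitative phase imaging (QPI) experiments.
    Provides explicit finite-difference (FTCS) heat-conduction solvers for
    pulsed mid-infrared absorption in spherical and layered geometries with
    Abel projection to photothermal phase images, a shot-noise budget and
    Fourier-domain phase reconstruction for off-axis digital holography,
    MIP image formation with background handling and signal-to-noise
    metrics, membrane water-permeability estimation from H2O/D2O exchange
    decay kinetics, multivariate curve resolution by alternating
    non-negative least squares for hyperspectral MIP stacks, and synthetic
    phantom-cell generators that supply ground truth for every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
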