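Package: lqt8sim
Title: Bidomain Simulation of LQT8/Timothy-Syndrome Ventricular Arrhythmogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reaction-diffusion simulation of reentrant ventricular
    arrhythmias in Long QT syndrome type 8 (Timothy syndrome). Couples the
    ten Tusscher-Panfilov 2006 human ventricular ionic model, extended with a
    wild-type/G406R-mutant L-type calcium current mixture and transmural IKs
    heterogeneity, to the Bidomain equations (with a monodomain reduction)
    discretised by Q1 hexahedral finite elements and semi-implicit operator
    splitting. Provides single-cell and 1D-cable pacing runners, idealized
    left-ventricular (truncated ellipsoid) mesh construction with rule-based
    fiber rotation, an S1-S2-S3-S4 programmed ventricular stimulation engine
    with reentry classification, and activation/repolarization dispersion
    post-processing on a transmural needle-electrode array.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
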