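Package: smfret
Title: Simulation, Classification, Correction and Kinetic Analysis of
    Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for automated analysis of camera-based single-molecule
    FRET (smFRET) intensity trajectories with one, two or three dyes and
    alternating laser excitation (ALEX).  Provides a labeled-trace
    simulator driven by continuous-time Markov kinetics with per-dye
    photobleaching; per-frame trace-category and state classifiers built
    on multi-scale temporal convolution networks trained within the
    package; automatic photobleaching-based determination of crosstalk,
    direct-excitation and detection-efficiency correction factors;
    accurate two- and three-color FRET efficiencies and dye-pair
    distances; transition density plots and mono-exponential dwell-time
    analysis; and a Gaussian-emission Baum-Welch hidden Markov model
    baseline for head-to-head kinetic comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
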