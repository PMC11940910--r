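Package: smt2state
Title: Two-State Mobility Analysis for Single-Molecule Tracking of Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule tracking (SMT) of
    membrane-bound proteins that switch between a slow, substrate-bound
    state and a fast, freely diffusive state. Provides jump-distance
    (squared-displacement) Rayleigh mixture fitting with BIC model
    selection, pooled Gaussian mixture fitting with diffusion
    coefficients shared across experimental conditions, dwell-time
    (residence-time) analysis with bootstrap errors and Levene tests,
    standardized-cell localization heat maps and zone statistics, plus a
    two-state trajectory simulator with localization noise and
    photobleaching that supplies ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
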