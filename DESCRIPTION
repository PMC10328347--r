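Package: cardioemu
Title: Gaussian-Process Emulation, Sobol Sensitivity Analysis and History
    Matching for Multiscale Cardiac Electromechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cell-to-organ global sensitivity analysis and
    calibration of multiscale cardiac electromechanics models. Provides
    Gaussian-process emulators with a linear prior mean and exponentiated
    quadratic or Matern-5/2 kernels, Saltelli designs with Jansen total-effect
    estimators and posterior-draw averaging, multi-wave history matching with
    implausibility measures, and desk-scale surrogate forward models: an
    anisotropic Eikonal activation solver on labelled grids, a calcium to
    active-tension cell surrogate, Guccione passive mechanics with thin-wall
    chamber inflation, and a closed-loop four-chamber lumped-parameter
    circulation that emits twenty pressure-volume features per run. A
    hierarchical pipeline chains sub-model emulation, parameter retention and
    plausible-region intersection into a whole-organ sensitivity analysis.
License: MIT
Encoding: UTF-8
Imports:
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
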