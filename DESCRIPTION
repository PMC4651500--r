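Package: leafgas
Title: Analysis and Simulation of Leaf Gas Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing and modelling leaf gas exchange data.
    Fits the Farquhar-von Caemmerer-Berry (FvCB) model of C3 photosynthesis
    to CO2 response (A-Ci) curves by nonlinear least squares, with standard
    errors, confidence intervals, mesophyll conductance and fixed-transition
    options, and batch fitting. Fits Ball-Berry-type stomatal conductance
    models (Ball-Berry, Leuning, and the optimality-based 1/sqrt(D) form).
    Solves the coupled photosynthesis-stomatal conductance model, optionally
    with leaf energy balance via the Penman-Monteith equation, and finds
    numerically optimal stomatal behaviour under the Cowan-Farquhar
    water-cost hypothesis. Includes a C4 photosynthesis simulator, humidity
    unit conversions, synthetic-data generators with known truth for testing
    fitting workflows, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
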