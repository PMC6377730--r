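Package: oscifit
Title: Regularised Parameter Estimation for Models of Biological Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated two-phase calibration of nonlinear ordinary
    differential equation models of biological oscillators. A first global
    estimation pass with an enhanced scatter search archives every cost
    evaluation; the archive drives per-parameter cost cut-offs, reduction of
    the parameter search box, and automatic tuning of a Tikhonov
    regularisation term; a second, regularised global pass produces an
    estimate with better predictive power. Includes forward-sensitivity
    integration from symbolically derived Jacobians, Fisher-information
    statistics, collinearity-based practical identifiability diagnostics, a
    synthetic-data generator for the bundled oscillator case studies
    (FitzHugh-Nagumo, Goodwin, Repressilator, enzymatic oscillator), and a
    plain-text model description format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
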