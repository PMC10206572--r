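Package: msmcox
Title: Markovian Multistate Cox Models with Individual Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Markovian multistate models from subject-level
    event-history data by transition-specific Cox proportional hazards
    regression, validates each transition fit with martingale, dfbetas and
    Schoenfeld residual diagnostics, and predicts the evolution of new
    individuals via Aalen-Johansen transition probabilities
    (state-occupancy curves, most-likely state, probability of an
    absorbing state by a horizon).  Predictive performance is assessed
    with the logarithmic score and a confusion matrix.  Includes
    non-parametric estimation (Nelson-Aalen cumulative intensities,
    kernel-smoothed instantaneous hazards, cumulative incidence), a
    clock-forward Markov path simulator with known truth for validation,
    and a small command-line driver for reproducible runs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
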