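Package: cperceiver
Title: Continuous Patient-State Attention Models for Irregular Clinical Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cross-attention (Perceiver) and transformer encoders for long
    clinical time series, together with continuous patient-state variants
    (COPER, CTransformer) that use neural ordinary differential equations to
    learn patient-health dynamics from irregularly observed time steps and
    resample a regular series at any requested times. Includes a synthetic
    ICU-like cohort generator with controllable missingness, an irregularity
    experiment harness for in-hospital-mortality prediction, analytic FLOP
    accounting for the attention encoders, Monte Carlo dropout predictive
    uncertainty with selective-prediction referral curves, and a command-line
    interface. All neural components (attention blocks, layer normalisation,
    LSTM, and a differentiable fixed-step Runge-Kutta solver) are implemented
    natively with hand-derived reverse-mode gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
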