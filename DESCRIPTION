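Package: swiftr
Title: SpO2 Waveform Forecasting and Hypoxemia Event Prediction for ICU Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-step-ahead forecasting of pulse-oximetry (SpO2) waveforms for
    critically ill patients, using only prior SpO2 values as inputs. Implements
    the SWIFT approach: an exponential saturation transform that magnifies
    differences near 100 percent, causal moving-average smoothing, supervised
    lag-matrix construction, a small LSTM regression network trained with Adam
    and best-epoch weight restoration (with 3-fold cross-validation over
    architecture and learning rate), and forecast-thresholded hypoxemia event
    prediction at the SpO2 < 92 percent threshold with per-stay and pooled
    evaluation metrics. Includes a seeded synthetic ICU cohort simulator with
    ground-truth desaturation events so the full pipeline is testable without
    access-restricted clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
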