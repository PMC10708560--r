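Package: vitalradar
Title: Continuous-Wave Radar Vital-Sign Simulation and Temporal Neural
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates the complex baseband return of a 24 GHz
    continuous-wave Doppler radar observing chest motion driven by
    heartbeat and respiration, builds labeled synthetic datasets across a
    signal-to-noise sweep, and trains four temporal neural network
    families (1D-CNN, TCN, Bi-LSTM, CRNN) for joint
    heart/respiration-rate regression and three-class physiological-state
    classification. Includes an FFT rate-estimation oracle, the full
    evaluation protocol (RMSE, MAE, R2, an adapted R2* for fixed-label
    blocks, confusion-matrix metrics), and reproducible experiment
    orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
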