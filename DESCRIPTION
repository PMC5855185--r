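Package: semgrip
Title: Handgrip Force Estimation from Surface EMG by Wavelet Scale Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates handgrip force from surface electromyography (SEMG)
    recorded during prolonged force-varying contractions. Extracts
    frame-wise intensities of Daubechies-2 continuous wavelet coefficients
    at integer scales 1-10, fits a no-intercept second-order polynomial
    SEMG-force model by ordinary least squares, quantifies each scale's
    nonlinear coupling to force with a variance-based Monte Carlo
    sensitivity analysis, and selects a wavelet scale combination by
    sequence combination analysis (SCA) that minimizes force-estimation
    root mean square error on validation data. Includes two classical
    baseline estimators (linear RMS-envelope model and the fixed
    scales-2-and-3 polynomial model) and a synthetic SEMG/force generator
    with force-dependent band amplitudes, fatigue-like low-frequency drift
    and broadband noise, so the full pipeline is testable without access
    to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    zoo
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
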