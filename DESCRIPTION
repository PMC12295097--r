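Package: fpcaforecast
Title: Functional Principal Component Forecasting of Regional Health-Workforce Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decomposes a region-by-year panel of positive counts (e.g. regional
    doctor counts) into a mean function, orthonormal regional basis functions and
    time-varying scores via functional principal component analysis on the log
    scale, forecasts the scores with automatically selected ARIMA models or a
    small LSTM network, and reconstructs coherent count forecasts with
    Monte-Carlo-dropout uncertainty. Includes rolling-origin expanding-window
    cross-validation with APE/MAPE accounting, a score-permutation significance
    test, a synthetic-panel generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
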