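Package: bayeserp
Title: Single-Channel P300 Brain-Computer Interface Analysis via Bayesian
    Single-Trial ERP Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing a single-channel P300
    oddball brain-computer interface. Provides a synthetic EEG epoch
    generator (autoregressive background activity plus a smooth
    event-related deflection at controllable signal-to-noise ratio),
    Bayesian single-trial ERP estimation with an integrated-white-noise
    smoothness prior and AR-whitened noise model (regularization tuned by
    the discrepancy criterion), a 78-element feature inventory, RBF-kernel
    support vector machine classification with repeated 80/20
    calibration-split model selection, session-protocol emulation, exact
    Wilcoxon signed-rank comparison of accuracy tables, and the Wolpaw
    information transfer rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
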