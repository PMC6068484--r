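Package: gaitphase
Title: Continuous Gait-Percent Estimation from Shank-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments walking recordings from a shank-worn inertial
    measurement unit (IMU) into gait cycles using force-sensitive-resistor
    (FSR) footswitch channels, labels every 10 ms sample with a continuous
    gait percentage, embeds the inertial signals with an exponentially
    delayed window, and trains a per-sensor branched feed-forward neural
    network that estimates and forecasts gait percent at 1% resolution.
    Includes the full metric suite (MSE, MAE, R-squared, percent-scale
    conversions), cycle-level train/validation splitting, a repeated-run
    evaluation protocol, and a synthetic multi-subject walking-signal
    generator so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
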