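Package: swinghr
Title: Explainable Home-Run Prediction from Bat-Sensor Swing Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Links bat-mounted IMU swing metrics (bat speed, bat mass, attack
    angle, on-plane efficiency, rotational acceleration) to annual home-run
    totals. Provides a rigid-ball flight simulator with Magnus lift, drag and
    side force for carry-distance validation of learned bat-speed thresholds,
    a speed chain converting between batted-ball, bat-head and sensor-reported
    speeds, a calibrated synthetic swing-cohort generator with planted
    nonlinear effects, per-player outlier filtering, random-forest / gradient
    boosting / linear / baseline regression models with a repeated
    player-subsampling evaluation protocol, and model-agnostic explanation
    tools implemented from first principles: partial dependence and ICE
    curves, exact Shapley attributions by coalition enumeration, and
    permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
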