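Package: pulsemet
Title: Real-Time Heart-Rate-Driven Energy Expenditure Estimation with a
    Deep Q-Network
Version: 0.1.0
Authors@R:
    person("pulsemet", "developers", email = "pulsemet@example.org",
           role = c("aut", "cre"))
Description: Estimates per-second energy expenditure (EE) from heart rate
    and demographics by learning a discrete activity-intensity coefficient
    with a deep Q-network, and predicting EE as resting metabolic rate
    (Mifflin-St Jeor) times (1 + coefficient).  Includes the classical
    closed-form estimators (indirect calorimetry from VO2, MET-based EE,
    the Keytel heart-rate regression), a synthetic generator for
    per-second wearable exercise sessions structured like the public WEEE
    protocol (sit/stand/cycle/run), a sliding-window episodic environment
    with a normalized absolute-error reward, replay-buffer DQN training,
    and an evaluation pipeline reporting overall and per-activity-segment
    mean absolute error for each estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
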