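Package: touchbandit
Title: Explore-Exploit State Decoding and Touch Variability Analysis for
    Touchscreen Restless Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for two-arm spatial restless
    bandit experiments run in touchscreen operant chambers. Provides the
    drifting reward-probability walk of the task, a reinforcement-learning
    choice-kernel (RLCK) agent with maximum-likelihood fitting, a
    transition-constrained three-state hidden Markov model that labels each
    trial as exploration or side-specific exploitation, trial-level spatial
    precision metrics for touch coordinates (successive Euclidean distance,
    Mahalanobis distance from aperture centroids, distance from the screen
    midline), bout segmentation with centroid-shift and density-contour
    area/perimeter geometry, stepwise-AIC linear mixed-model selection over
    the resulting metric tables, and a synthetic cohort generator that
    carries the state, sex and prior-reward effect structure the analysis
    is designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
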