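Package: drowsefuse
Title: Self-Adaptive Fatigue-Driving Recognition by Fuzzy-Neural Feature
    Fusion and Dempster-Shafer Evidence Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes driver fatigue states (non-fatigue, moderate
    fatigue, severe fatigue) from windowed facial-expression and
    vehicle-behavior measurements.  Eight drowsiness features (blink
    frequency, eye-closed duration, mean eye-opened level, yawning
    frequency, percentage of non-steering, steering-angle standard
    deviation, abnormal lane-deviation frequency, speed standard
    deviation) are extracted from raw per-frame and per-sample streams,
    screened by Kolmogorov-Smirnov normality and Pearson correlation
    tests, and fused at the feature level by two Takagi-Sugeno fuzzy
    neural networks whose structure comes from subtractive clustering and
    whose parameters are trained by particle swarm optimization.  The
    network outputs become dynamic basic probability assignments that are
    fused at the decision level by a conflict-aware Dempster-Shafer
    combination with belief-factor discounting and temporal recursion,
    then converted to a fatigue-state decision.  Includes a calibrated
    synthetic-session generator, EEG band-power / observer / sleepiness
    scale ground-truth assessment utilities, broom-style tidiers, and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
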