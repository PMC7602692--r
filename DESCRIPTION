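Package: solewalk
Title: Activity Recognition from Smart-Shoe Plantar-Pressure Insoles
Version: 0.1.0
Authors@R: person("Solewalk", "Developers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for recognizing daily-life activities from multichannel
    plantar-pressure recordings collected with instrumented insoles (seven
    force sensors per foot, sampled at 100 Hz). Provides calibrated reading
    and zero-phase Butterworth smoothing of 14-channel force time series,
    overlapping-window segmentation, a catalog of up to 167 window features in
    five families (general statistics, peak analysis, gait phase, frequency
    domain, pressure distribution) whose availability depends on the sensor
    subset, subject-wise random-forest training and evaluation with a
    multi-hold-out protocol, recursive feature elimination, and sweeps over
    window length and sensor configuration. A synthetic gait-pressure
    simulator generates labeled cohorts with per-activity stance-pulse
    structure so the full pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    ranger,
    Rcpp,
    signal,
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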