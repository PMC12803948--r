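Package: pestmle
Title: Adaptive PEST-MLE Estimation of the TMS Resting Motor Threshold
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequential maximum-likelihood threshold hunting (PEST-MLE) for
    transcranial magnetic stimulation resting motor threshold (RMT)
    estimation. Fits a one-parameter cumulative-Gaussian psychometric
    function to binary motor-evoked-potential outcomes with virtual boundary
    anchors, runs the 30-trial adaptive session loop, derives trial outcomes
    from raw EMG traces, simulates virtual subjects with right-skewed MEP
    amplitudes and day/session threshold drift, and evaluates precision and
    accuracy convergence together with test-retest reliability (ICC(2,1),
    within-subject SD, reproducibility coefficient, standard error of
    measurement, Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
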