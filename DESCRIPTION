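Package: tracefear
Title: Measurement Pipeline for Human Trace Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying conditioned responses in human trace fear
    conditioning with long (15 s) trace intervals. Generates reinforcement
    schedules under a run-length randomization constraint, simulates
    multi-channel psychophysiological recordings (startle EMG, skin
    conductance, pupillometry, ECG, respiration) with known ground truth,
    implements per-modality preprocessing chains and trial-wise response
    quantification (peak scoring, GLM inversion with canonical or fitted
    response functions, constrained nonlinear inversion of a three-burst
    sudomotor model), and provides the statistical layer used to calibrate
    such measurements: cluster-level permutation tests on trial-averaged
    time courses, trial-averaging effect-size calibration, linear
    mixed-effects models with habituation regressors, and noncentral-t
    power planning.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
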