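Package: ppgbp
Title: Cuffless Blood Pressure Estimation from PPG Waveform Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cuffless blood-pressure estimation from
    photoplethysmogram (PPG) waveforms over month-long monitoring. Includes a
    seeded generator of longitudinal synthetic PPG/BP cohorts with per-subject
    physiology, slow seasonal drift and corrupted-beat episodes; beat-level
    preprocessing (zero-phase Butterworth filtering, beat segmentation,
    skewness-based signal quality selection); notch-free waveform features
    (PIR, DTR, reflection-index surrogate, spectral band areas); partial least
    squares, locally weighted PLS with Mahalanobis similarity, and Gaussian
    process regressors; and an evaluation layer implementing initial and
    intermittent calibration schemes with leakage-free rolling prediction,
    individual versus generalized training strategies, an interpolation
    baseline, error metrics and paired significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
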