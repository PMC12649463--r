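Package: blinkpath
Title: Eye-Blink Detection from Eye-Aspect-Ratio Signals with Psychometric
    Scoring and Mediation Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spontaneous eye-blink rate from facial-landmark
    derived eye-aspect-ratio (EAR) time series and relating it to psychometric
    measures. Implements EAR computation from 6-point eye landmarks, threshold-based
    blink segmentation with duration filtering, personalized threshold calibration by
    bisection against a manual blink count, BFI-2 and PSS-14 scoring with Cronbach's
    alpha and SPSS-compatible descriptives, Pearson correlation matrices, and a
    saturated standardized mediation path model (X -> M -> Y) with suppression
    detection and a bootstrap confidence interval for the indirect effect. A
    synthetic-data module generates EAR signals with known blink ground truth,
    correlated trait/stress/blink samples, and keyed Likert item matrices so the
    whole pipeline can be exercised without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
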