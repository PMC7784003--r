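Package: fogkit
Title: Freezing-of-Gait Detection from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based detection and characterization of freezing-of-gait
    (FoG) episodes in Parkinson's disease from synchronized inertial sensors on
    the feet (or shins) and lumbar region. Implements per-second dual-criterion
    FoG flagging inside walking bouts (bilateral medio-lateral gyroscope
    correlation combined with an antero-posterior accelerometer freeze ratio),
    merging of episodes separated by short hesitations, clinically motivated
    duration categories, daily-life freezing and turning outcome measures over
    30-minute windows and weeks, a labelled synthetic-signal generator for
    end-to-end validation, and the evaluation statistics used for
    rater-agreement studies (ICC(2,1) with confidence intervals, ROC/AUC with
    confusion metrics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pROC,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
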