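Package: hemowave
Title: Arterial-Waveform Machine Learning for Early Hemorrhage Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-level feature extraction from arterial blood pressure
    waveforms and decision-tree-ensemble modelling of blood-loss metrics for
    early hemorrhage detection in canines. Provides a synthetic hemorrhage
    waveform simulator emulating a controlled-hemorrhage protocol (baseline,
    hemorrhage to a mean-arterial-pressure target or 40% estimated blood
    volume, shock hold), FIR preprocessing, fiducial landmark detection
    (pulse foot, half-rise, systolic peak, dicrotic inflection with half-drop
    fallback), a documented multi-family per-beat feature registry, the
    hemorrhage metrics BLVM, PEBL and HemArea, minimum-redundancy
    maximum-relevance feature ranking, bagged regression trees with
    leave-one-subject-out cross-validation, and detection-latency evaluation
    against mean arterial pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    rpart,
    MASS,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
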