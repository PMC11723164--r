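Package: taskbeta
Title: Task-State EEG Multitaper Pipeline for Cross-Subject
    Alzheimer's-Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, a task-state
    EEG analysis for cross-subject Alzheimer's-risk classification:
    multitaper time-frequency estimation with Slepian (DPSS) tapers,
    time-frequency-space feature reduction to region-by-band feature
    spaces (F216/F24), mass-univariate t-test screening with
    Benjamini-Hochberg false-discovery-rate control, and cross-subject
    Leave-p%-Subjects-Out validation of four classifiers with
    class-weighted metrics and aggregated percentage confusion matrices.
    Includes a synthetic event-related EEG generator with a planted
    prefrontal beta-band group effect so the full pipeline is testable
    without access to the source database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    ranger,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
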