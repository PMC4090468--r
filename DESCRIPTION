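Package: seizpred
Title: Dynamic-Update Seizure Prediction from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An online epileptic-seizure prediction pipeline for multichannel
    intracranial EEG. Windows of the recording are decomposed by empirical mode
    decomposition, the Hilbert instantaneous phases of the intrinsic mode
    functions are modelled by one-step extreme-learning-machine (ELM)
    regression, and the flattened ELM output-weight matrix of each window is
    used as a phase-interaction feature. A second ELM classifies windows as
    preictal or interictal, a preictal-density rule raises alarms, and two
    fixed-capacity sample pools (preictal and interictal) are updated online
    after false or missed alarms using Mahalanobis-distance sort-and-retain
    rules, after which the classifier is refit. Includes event-based
    evaluation (sensitivity, false-positive rate per hour, advance time,
    performance index) and a coupled-oscillator synthetic EEG generator with
    annotated seizures, a preictal synchronization ramp, optional spectral
    drift, and 50 Hz line contamination.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    data.table,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
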