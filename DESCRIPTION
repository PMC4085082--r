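Package: BeatEnsemble
Title: Hierarchical Inter-Patient Heartbeat Classification with Random
    Projections and SVM Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for AAMI-style inter-patient classification of ECG
    heartbeats. Beats segmented around annotated R peaks are z-normalized,
    mapped to low-dimensional feature vectors through a bank of seeded
    Gaussian random matrices (pseudo-inverse projection), and classified by
    a majority-vote ensemble of RBF-kernel support vector machines to
    detect ventricular ectopic beats; the remaining beats are screened for
    supraventricular ectopic beats with an RR-interval-ratio threshold
    selected on the training records. Includes leave-one-recording-out
    cross-validation with summed confusion matrices, per-recording
    performance reports, a plain-text two-lead recording format, and a
    seeded synthetic ECG generator for download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
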