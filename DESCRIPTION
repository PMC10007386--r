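Package: beatae
Title: Beat-by-Beat Atrial Fibrillation Detection from Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for beat-by-beat discrimination of atrial fibrillation
    (AFib) from normal sinus rhythm (NSR) in single-lead ECG. Provides a
    seeded synthetic ECG generator with labelled rhythms, a preprocessing
    chain (0.5 Hz high-pass FIR filtering, adaptive-threshold QRS detection,
    fixed-length R-centred beat segmentation with second-R-peak zero-padding,
    cosine-distance outlier rejection), the per-beat LCSD rhythm-irregularity
    statistic, a small dense neural-network core (plain, sparse and
    supervised autoencoders plus an MLP classifier) trained with Adam and
    early stopping, and an evaluation layer with portion- and patient-level
    splits, class balancing, cross-validation, ROC threshold selection and
    Mann-Whitney U validation. Readers for WFDB-style records and label
    manifests are included so real Holter or handheld-device recordings can
    be analysed with the same pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
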