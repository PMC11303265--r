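Package: microstatr
Title: Resting-State EEG Microstate Analysis with AAHC Clustering and
    Diagnostic Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete resting-state EEG microstate pipeline: global field
    power (GFP) computation and peak extraction, polarity-invariant
    atomize-and-agglomerate hierarchical clustering (AAHC) of GFP-peak
    topographies, two-level (subject and group) template derivation with
    canonical A-D labeling, backfitting by spatial correlation, global
    explained variance, temporal dynamics (mean duration, time coverage,
    occurrence, transition syntax), clinical audiometric and posturographic
    score formulas, normality-gated group statistics with mixed-design
    ANOVA and Bonferroni post hoc tests, and a linear-SVM diagnostic
    classifier evaluated by nested leave-one-out cross-validation with
    sequential backward feature selection and label-permutation testing.
    A semi-Markov synthetic EEG and cohort generator provides ground truth
    for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
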