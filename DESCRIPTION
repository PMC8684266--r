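Package: medcontext
Title: Medical-Context Vector Spaces for Clinical Chart Review Query Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents clinical terms by their normalized usage frequencies
    across ten non-textual medical contexts (author department and staff type,
    concurrent ICD/CPT/chief-complaint events, patient age and gender, note
    type and note sections) and compares terms by per-context cosine
    similarity. A chart reviewer's semantic preference -- which similar terms
    they would highlight -- is learned from small label sets by logistic
    regression (or random forest / SVM) on the ten per-context similarities to
    a topic word, yielding interpretable context weights. Includes the full
    evaluation machinery (importance-cutoff sweep, stratified ten-fold
    cross-validation with AUROC, one-sided Mann-Whitney feature-space
    comparison, learning curves) and a synthetic EMR note generator with
    planted reviewer preferences so every component is testable without
    access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
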