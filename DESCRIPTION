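Package: ssoddi
Title: Sparrow-Search-Optimised Multilabel LSTM Autoencoder for Drug
    Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts drug-drug and drug-target interactions from
    positive-unlabeled bipartite interaction matrices with a multilabel
    LSTM autoencoder whose hyperparameters are tuned by sparrow search
    optimisation. Includes drug-blinding text preprocessing for
    interaction sentences, a lexicon-based interaction-severity grader,
    seeded cross-validation with AUC/AUPR ranking metrics, top-k%
    unlabeled-pair labeling curves, a seeded low-rank synthetic data
    generator, and a YAML-configured end-to-end pipeline with a thin
    command-line wrapper.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
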