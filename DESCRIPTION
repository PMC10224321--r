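Package: fitrank
Title: Protein Fitness Prediction with Sequence Encodings, Resampling and
    Multi-Criteria Ranking
Version: 0.1.0
Authors@R:
    person("Fitness", "Maintainer", role = c("aut", "cre"), email = "maintainer@example.org")
Description: An evaluation pipeline for discriminative protein fitness models
    trained on enrichment-derived deep-sequencing data. Cleans and labels
    sorted-library read-count tables, encodes amino-acid sequences (one-hot,
    physiochemical descriptors, pluggable language-model embedding adapters),
    rebalances severely imbalanced classes (undersampling, random
    oversampling, SMOTE), trains L2-regularised logistic classifiers and
    random-forest regressors across replicate seeds, combines encodings by
    concatenation and majority voting, and ranks all encoding-by-sampling
    alternatives with entropy-weighted TOPSIS plus ANOVA, Tukey and MANOVA
    validation. Ships a synthetic-data generator emulating affibody
    enrichment experiments and stability (melting temperature) tables so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
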