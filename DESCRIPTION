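Package: increclm
Title: Incremental Fine-Tuning of Chemical Language Models for Structural Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biasing a SMILES-generating recurrent language model toward
    increasingly potent members of a structure-activity relationship (SAR) series.
    Implements SMILES standardization, tokenization and augmentation, potency-staged
    data splitting, pretraining and incremental fine-tuning of an LSTM chemical
    language model with checkpoint restoration, multinomial temperature sampling,
    perplexity-based design ranking and filtering, rediscovery scoring against a
    withheld high-potency holdout, sampling statistics, and distributional similarity
    metrics. Includes a synthetic scaffold-plus-substituent chemical universe with a
    known pseudo-potency landscape for desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: Open Babel (obabel on the PATH)
RoxygenNote: 7.3.3
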