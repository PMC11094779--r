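Package: gpcrstab
Title: Structure-Based Prediction of Mutation Effects on GPCR Thermostability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in apparent melting temperature (dTm) caused
    by single-point mutations in G protein-coupled receptors from a wild-type
    structure. Residue environments are summarised as graph-based structural
    signatures (cumulative pharmacophore pair-distance counts over a cutoff
    grid) together with a pharmacophore change vector and auxiliary
    sequence/structure features (substitution matrices, AAindex pair matrices,
    relative solvent accessibility, residue depth, membrane topology flags).
    Tree-ensemble regressors with greedy forward feature selection under
    k-fold cross-validation rank candidate mutations for thermostabilising
    protein engineering. Includes a synthetic alpha-helical bundle generator
    with planted linear labels so the whole pipeline is testable without
    external data, plus evaluation utilities for classification-by-regression
    benchmarking against ddG predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
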