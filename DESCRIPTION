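Package: pessr
Title: Protein Fold Recognition in an Empirical Structure Feature Space
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps protein domain sequences into a feature space whose
    coordinates are compatibility scores against a fixed library of
    structure templates (an empirical kernel map), and classifies SCOP
    folds in that space with a first-nearest-neighbour classifier, a
    one-vs-all linear support vector machine, and a two-phase combined
    scheme. Includes distance-threshold rejection of queries whose fold
    is unlikely to be represented in training, calibration of that
    threshold by a leave-own-fold-out procedure, detection of candidate
    novel-fold clusters among rejected domains via t-SNE embedding and
    density-based clustering, SCOPe/Astral-style data ingestion and
    identity-based redundancy filtering, cross-validated evaluation, and
    a synthetic data generator for end-to-end testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    igraph,
    optparse
Config/testthat/edition: 3
biocViews: Classification, Proteomics, StructuralPrediction, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ScoreMatrix.R'
    'TemplateLibrary.R'
    'accessors.R'
    'calibration.R'
    'classify-nn.R'
    'classify-svm.R'
    'cli.R'
    'datasets.R'
    'evaluation.R'
    'novelty.R'
    'persistence.R'
    'pessr-package.R'
    'score-providers.R'
    'standardize.R'
    'synthetic.R'
    'tsne.R'
    'utils.R'
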