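Package: hierDTI
Title: Hierarchy-Regularized Joint Embedding for Drug-Target Interaction
    Prediction in Hyperbolic and Euclidean Latent Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pairwise drug-target interaction (DTI) prediction with a joint
    drug-target latent space that simultaneously embeds a priori biological
    hierarchies (ATC-style drug trees, kinome/nuclear-receptor protein trees,
    MeSH-style graphs). Provides Lorentz (hyperboloid), Poincare-ball and
    Klein model primitives; feed-forward encoders with a Euclidean dot-product
    or squared-Lorentzian-distance prediction head; a ranking-based hierarchy
    regularizer driven by lowest-common-ancestor distance matrices; expected
    dendrogram purity and AUC evaluation; a Poincare-disk dimensionality
    reduction with bottom-up hierarchy-tree embedding and translation-based
    navigation; and a synthetic benchmark generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'hierarchy.R'
    'mlp.R'
    'model.R'
    'evaluation.R'
    'latentviz.R'
    'synthdata.R'
    'workbench.R'
    'cli.R'
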