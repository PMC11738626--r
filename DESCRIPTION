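Package: poseMIL
Title: Multi-Instance Learning on Docking-Pose Bags for Binding-Affinity
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-ligand binding affinity from bags of molecular
    docking poses using attention-based multi-instance learning (MIL). Each
    protein-ligand entity is represented as a bag of pose instances; graph
    neural network backbones (a spatial graph convolutional network over
    covalent/noncovalent distance edges, and an E(n)-invariant graph network
    over a radius graph) embed each pose, and a permutation-invariant
    attention head pools the bag into a single predicted affinity in pK
    units. Includes Pafnucy-style 19-dimensional atom featurization, graph
    construction, two-stage (backbone-then-head) training with an RMSprop
    milestone schedule, Top/Avg pose baselines, good-pose stratification,
    pairwise-RMSD consistency summaries, bag-size ablation, and a synthetic
    complex generator so the whole pipeline is testable without external
    structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
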