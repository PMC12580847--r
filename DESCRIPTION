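Package: tsflow
Title: Transition-State Geometry Generation by Equivariant Conditional Flow Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates 3D transition-state geometries for single-step chemical
    reactions directly from atom-mapped 2D reaction graphs. Reactions are encoded
    as a condensed graph of reaction (CGR) with dual reactant/product labels, a
    time-conditioned E(3)-equivariant vector-field network is trained by
    optimal-transport conditional flow matching (Kabsch-aligned linear
    interpolation paths), and geometries are sampled by Euler integration of the
    learned probability-flow ODE with median-based sample aggregation. Includes
    geometry evaluation metrics (distance MAE, Kabsch RMSD, angle error, steric
    clash), random / reaction-core / barrier-height dataset splits, a synthetic
    reaction fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
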