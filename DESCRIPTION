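Package: pamatch
Title: Probabilistic Analogical Mapping Between Attributed Part Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic analogical mapping (PAM) between attributed
    graphs built from labeled object parts: spatial-relation edge
    embeddings for 2D keypoints and 3D point clouds, graduated-assignment
    inference with inverse-temperature annealing and Sinkhorn
    normalization, part-level graph construction from clustered point
    clouds, marker transfer via a three-distance metric, evaluation
    metrics with chance normalization, a Hartigan dip based
    response-variability analysis, and synthetic fixture generators with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    jsonlite,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'relations.R'
    'graph.R'
    'pam.R'
    'pointcloud.R'
    'synth.R'
    'metrics.R'
    'dip.R'
    'io.R'
    'RcppExports.R'
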