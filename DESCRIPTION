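Package: walkaggr
Title: Random-Walk Node Embeddings with Distance-Weighted Neighborhood
    Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised network representation learning for node
    classification. Self-representational node vectors are learned by
    truncated random walks and skip-gram with negative sampling; one-hop
    neighborhoods are then aggregated with weights derived from
    center-neighbor Euclidean distances in embedding space, either by a
    closed-form softmax over sigmoid-normalized distances or by one-head or
    multi-head self-attention trained on a distance-regression task.
    Self and local vectors are concatenated and fused back to the original
    dimensionality by principal component analysis. Includes a repeated
    random-split one-vs-rest evaluation protocol (Micro-F1) and seeded
    generators for community-structured labelled graphs used as synthetic
    benchmarks for biological and social networks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
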