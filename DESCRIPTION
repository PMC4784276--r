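Package: crossclust
Title: Replicable Patient Subtype Discovery Across Independently
    Clustered Expression Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers replicable patient subtypes ("meta-clusters") across a
    collection of independently normalized gene-expression datasets without any
    between-dataset batch correction. Each dataset is clustered on its own by
    consensus k-means with PAC-based model selection; clusters from different
    datasets are then compared by nearest-centroid assignment under Pearson
    correlation, with permutation P values obtained from geometry-preserving
    random rotations of the reference centroid set. Cluster pairs that are
    reciprocal best matches and pass similarity, nearest-neighbor-fraction and
    P value thresholds are joined into a weighted network, and Girvan-Newman
    community detection yields the final meta-clusters. Includes a synthetic
    multi-dataset archetype simulator with an edge-level true/false positive
    rate evaluation harness, and meta-analytic (Hedges' g) marker-gene scoring
    per subtype.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
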