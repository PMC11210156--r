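Package: clustall
Title: Robust Consensus-Based Patient Stratification for Mixed-Type
    Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised stratification of patient cohorts described by
    mixed-type clinical variables (numeric, binary, nominal, ordinal),
    with principled handling of missing values. Highly correlated
    features are collapsed through a feature dendrogram whose cut levels
    ("depths") each yield a low-dimensional principal-component
    embedding; every embedding is clustered under multiple distance
    metrics (correlation, Gower) and algorithms (k-means, k-medoids,
    hierarchical) with the number of clusters chosen by consensus of
    three internal validity indices. Candidate stratifications are then
    filtered by bootstrap cluster-wise Jaccard stability and grouped by
    pair-counting Jaccard distance so that only partitions robust to
    both patient resampling and pipeline parameter changes are
    reported. Missing data are handled by chained-equations multiple
    imputation with per-imputation clustering consolidated through a
    patient co-assignment matrix. Includes a mixed-type synthetic
    cohort generator with planted subgroups, minimal-signature
    extraction by forward-backward feature selection, and k-nearest
    neighbour label transfer to external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    MASS,
    nnet,
    jsonlite,
    yaml,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    class,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
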