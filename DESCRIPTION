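Package: tinnbench
Title: Bootstrapped Semi-Supervised Benchmarking of Tinnitus Subphenotype
    Clusterings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks combinations of dimensionality reduction methods
    (PCA, factor analysis of mixed data, t-SNE) and clustering algorithms
    (k-means, DBSCAN) on mixed-type patient questionnaire tables that carry
    a partial endotype labeling, such as tinnitus case-history databases.
    Clusterings are scored by the silhouette, by a bootstrapped
    four-clustering stability protocol based on adjusted mutual information
    with an exact hypergeometric expectation, and by the V-measure at a
    homogeneity-weighted beta against the partially diagnosed endotypes.
    Includes missing-value filtering, iterative random-forest imputation,
    stratified 50-50 partitioning, grid-search orchestration, eligibility
    filtering and shortlisting, pooled Cohen's D cluster profiling, and a
    synthetic cohort generator with planted endotype structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    ranger,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
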