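Package: scICP
Title: Cell Population Identification by Iterative Clustering Projection
    and Consensus Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cell populations from single-cell RNA-seq
    expression matrices using iterative clustering projection (ICP), a
    self-supervised algorithm that repeatedly trains an L1-regularized
    logistic-regression classifier on a clustering and replaces the
    clustering by the classifier's own predictions whenever that raises
    the adjusted Rand index between the two.  Many independent ICP runs
    are merged into a joint cluster-probability matrix, reduced by
    principal component analysis and clustered hierarchically with
    Ward's method to obtain a high-resolution consensus clustering,
    with the number of clusters selected by the silhouette method.
    Includes two-dimensional embedding of the consensus space (t-SNE or
    UMAP), Wilcoxon rank-sum marker-gene detection with Bonferroni
    correction, readers and writers for Matrix-Market/10x-style and
    dense delimited expression matrices, library-size log-normalization
    of UMI counts, and a synthetic-data generator with planted
    populations and marker genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils,
    glmnet,
    cluster,
    RSpectra,
    Rtsne,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
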