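Package: rwce
Title: Random-Walk Cluster Ensembles for Multi-Omics Consensus Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus clustering by random-walk refinement of a cluster
    ensemble. Base k-means clusterings of one or more omics views are pooled
    into a binary instance-cluster matrix; a Jaccard cluster network is
    diffused by random walk with restart; the refined instance-cluster
    association matrix is partitioned as a bipartite graph with normalized-cut
    spectral clustering and eigengap model selection. Applied hierarchically,
    the refinement integrates multiple data types (e.g. mRNA expression,
    miRNA expression, DNA methylation) into a single subtyping. Includes a
    multi-view Gaussian-mixture simulator with matched survival outcomes and
    evaluation metrics (mean silhouette, adjusted Rand index, log-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
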