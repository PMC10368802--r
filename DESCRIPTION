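Package: clustercode
Title: Marker Co-Expression Code-Scoring and Significance-Based Merging
    of Single-Cell Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether tentatively defined single-cell RNA-seq clusters
    are transcriptionally distinct, and merges those that are not. Each cell
    is scored for co-expression of every cluster's marker-gene set via the
    log inverse joint probability of the observed expression levels
    ("code-scoring"), with cells co-expressing the negative gene sets that
    distinguish heavily overlapping clusters filtered to zero. Cluster pairs
    are then compared with bi-directional Welch tests on quantile-summarized
    scores and mutually non-significant pairs are merged, correcting
    deliberate over-clustering. Includes a negative-binomial count simulator
    in which groups are defined by unique marker-gene combinations, and
    ROC-based benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rhdf5,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
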