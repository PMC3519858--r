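Package: ranetkit
Title: Disease-Perturbed Network Discovery from Multi-Study Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers disease-dominant gene sets from multiple expression
    studies by non-negative matrix factorization (NMF) soft clustering of
    cross-normalized log2 fold-change matrices, with element-permutation
    significance thresholds; scores gene sets against annotation collections
    by empirical resampling enrichment with an exact hypergeometric oracle;
    reconstructs the disease-perturbed protein-interaction subnetwork and
    computes module enrichment scores for overlay signatures; and identifies
    key transcription factors and interaction hubs by resampling tests on
    target counts and first/second-neighbor counts. Includes a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
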