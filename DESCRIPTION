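Package: modcore
Title: Core Disease-Module Extraction from Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts statistically significant "core" modules from
    undirected biological networks by maximising the community-extraction
    criterion with a local-moving heuristic guided by sample-and-seed
    initialisation, and screens the extracted modules with a B-score
    significance measure under a configuration-model null that keeps
    module-internal edges fixed. Also provides jackknife Fisher-z
    co-expression network construction from expression matrices,
    module-set comparison (Jaccard reproducibility and conservation
    scores, Hungarian best-matching, common-module intersection),
    module activity statistics (expression signatures, log fold change,
    Jonckheere-Terpstra trend test, hypergeometric gene-set enrichment
    with FDR control), and ground-truth synthetic generators for planted
    module networks and block-correlated expression cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
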