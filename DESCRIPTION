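Package: coexmeta
Title: Multi-Population Co-Expression Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cross-dataset gene co-expression networks by combining
    per-dataset Pearson correlations through rank-order statistics and the
    joint cumulative distribution of uniform order statistics, clusters the
    resulting weighted networks with map-equation (Infomap) consensus
    clustering, scores cluster significance against degree-preserving null
    models, performs hierarchy-aware Gene Ontology and flat pathway
    enrichment, and quantifies physical (hypergeometric overlap) and
    functional (Wang semantic similarity with best-match averaging and an
    empirical null) similarity between clusters. Includes a synthetic-data
    generator that plants co-expressed gene modules across negative-binomial
    count and Gaussian intensity datasets so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
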