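Package: menanet
Title: Molecular Ecological Network Analysis with Random Matrix Theory Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds microbial co-occurrence networks from OTU abundance
    tables using the random matrix theory (RMT) approach: Pearson
    correlations on log-transformed abundances are thresholded at the point
    where the nearest-neighbour spacing distribution of the correlation
    matrix eigenvalues transitions from Wigner-Dyson (GOE) to Poisson
    statistics. Provides the full downstream panel used in molecular
    ecological network analysis: topological indices, greedy modularity
    modules, Zi-Pi node roles, module eigengenes and their hierarchy,
    degree-preserving null models, Mantel tests and module-environment
    correlation heatmaps, alpha-diversity indices, and a synthetic
    community generator with planted modules and environmental coupling
    for end-to-end validation. Networks are exported as GraphML and
    Cytoscape-compatible edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
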