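Package: richclubnet
Title: Rich-Club Organization and Communication Structure of Directed Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretical analysis of binary directed connectomes, centred on
    statistically validated rich-club detection. Provides degree-preserving randomized
    and latticized null-model ensembles, directed small-world metrics (clustering,
    efficiency, gamma, lambda, sigma, omega), spectral optimization of directed
    modularity with connector-hub classification, four node-centrality measures with a
    consistency score, a 13-class directed triad census with apex and star-motif
    statistics, k-core decomposition, and exhaustive shortest-path analytics
    (path counts, rich-club path participation, positional degree profiles, net
    directional flow into and out of the rich club, and Euclidean communication cost).
    A synthetic-network generator with planted modules and a planted rich club makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
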