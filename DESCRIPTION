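Package: mwclique
Title: Exact Maximum Weight Clique Search in Vertex-Weighted Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact branch-and-bound search for a maximum weight clique in an
    undirected vertex-weighted graph, using a weighted greedy-coloring upper
    bound and an optional variant that dynamically recomputes vertex degrees
    within induced candidate subgraphs to tighten the bound at the lower
    levels of the recursion. Includes a reader/writer for the ASCII DIMACS
    clique format with a vertex-weight line dialect, a random weighted-graph
    generator (G(n,p) edges with rounded positive normal weights), a naive
    brute-force reference solver for verification, and a shuffle-and-repeat
    benchmarking harness. Maximum weight cliques in correspondence (product)
    graphs encode maximum common substructures of molecules, the motivating
    application in drug discovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
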