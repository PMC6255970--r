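Package: crosstalkkit
Title: Pathway Cross-Talk Networks and Maximal-Scoring Subnetworks for
    Candidate Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taking a prioritized candidate gene list (such as a
    drought stress related gene panel) through over-representation analysis,
    pathway cross-talk network construction, and maximal-scoring subnetwork
    extraction from a protein-protein interaction network. Enrichment uses a
    one-sided hypergeometric (Fisher's exact) test computed in log space with
    Benjamini-Hochberg adjustment per ontology stratum. Cross-talk edges are
    scored by Jaccard and overlap coefficients with shared-gene and
    significance filters. Subnetworks are found by fitting a beta-uniform
    mixture to node p-values, converting a false discovery rate target into a
    score threshold, projecting the network to a minimum spanning tree (both
    Prim's and Kruskal's algorithms), and solving the maximum-weight connected
    subtree exactly by dynamic programming, with an exhaustive oracle for small
    instances. A synthetic-data generator produces gene universes, pathway
    collections with controlled overlap, enriched candidate sets, and
    interaction graphs with planted signal modules so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
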