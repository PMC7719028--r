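Package: vhconnect
Title: Structural Connectome Subnetworks, Controllability and Regional Gene
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain linking loss of a structural-connectome
    subnetwork to network controllability and regional gene co-expression.
    Implements network-based statistics with nuisance covariates and
    Freedman-Lane permutation, average controllability of the discrete
    linear network dynamics via the controllability Gramian, weighted gene
    co-expression network analysis with region-as-sample design (signed
    adjacency, topological overlap, tree-cut module detection with k-means
    refinement, module eigengenes, module-trait biweight midcorrelation),
    and expression-weighted cell-type enrichment with a covariate-matched
    bootstrap. A synthetic-data module generates cohorts of weighted
    connectomes, a regional expression atlas and a cell-type reference with
    known planted structure so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
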