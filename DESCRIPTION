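Package: graminet
Title: Inter-Domain Ecological Networks Between Grasses and Soil Microbes
Version: 0.1.0
Authors@R: person("Graminet", "Developers", role = c("aut", "cre"),
    email = "maintainers@graminet.dev")
Description: Tools for linking alpine-grassland grass productivity and
    diversity to soil archaeal, bacterial and fungal communities.
    Implements alpha/beta diversity with seed-controlled rarefaction,
    grassland-type group statistics (Kruskal-Wallis with Dunn post-hoc
    compact letters, Spearman screens, PERMANOVA), distance-decay
    regressions with cross-group slope contrasts, three-way variance
    partitioning on canonical correspondence analysis inertia, SparCC
    compositional correlation with bootstrap significance, direct-effect
    deconvolution of association networks, environmental/distance link
    pruning, bipartite network topology (connectance, clustering, NODF
    nestedness), robustness and vulnerability with degree-preserving null
    ensembles, and Mantel / partial Mantel connectivity tests. Includes a
    synthetic-community generator with planted ground truth emulating a
    multi-site grassland transect study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
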