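Package: RLQspace
Title: Extended RLQ, Fourth-Corner and Null-Model Dispersion Analysis of
    Trait-Environment-Phylogeny-Space Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trait-based community assembly analysis on forest
    dynamics plot data. Implements the five-matrix extension of RLQ
    co-inertia ordination that couples an environmental table and a
    spatial eigenvector basis on the site side with principal-coordinate
    representations of trait and phylogenetic distances on the species
    side, linked through a site-by-species abundance matrix. Provides
    fourth-corner permutation tests (row and column null models and
    their conservative combination), abundance-weighted mean pairwise
    distance with tip-shuffle null models yielding the net relatedness
    index (NRI) and the standardized effect size of dendrogram-based
    trait distance, Moran eigenvector maps, Moran's I permutation tests,
    and an intercept-only simultaneous autoregressive error model for
    spatially corrected inference. A synthetic forest-plot generator
    with tunable phylogenetic signal and environmental filtering
    strength supplies ground-truth test beds, and a config-driven
    pipeline reproduces the full multi-scale analysis sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
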