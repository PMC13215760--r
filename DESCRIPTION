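Package: evoregio
Title: Phylogenetic Regionalization with Evoregions and Phyloregions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates biogeographic regions from a phylogeny and a gridded
    presence/absence matrix using two complementary approaches: evoregions
    (phylogenetic fuzzy-weighting, principal coordinates of phylogenetic
    structure, and discriminant-refined k-means clustering) and phyloregions
    (branch-based Simpson phylogenetic beta diversity with UPGMA clustering
    and an explained-variation rule for the number of clusters). Also
    provides species-region affiliation, ancestral-region reconstruction by
    stochastic character mapping under an equal-rates Mk model, phylogenetic
    correspondence analysis ranking lineage contributions, and V-measure
    congruence tests between regionalizations with spatially contiguous
    randomization nulls and standardized effect sizes. A synthetic-data
    generator of planted contiguous landscapes and clade-structured
    occurrence matrices supports validation and worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    phytools
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
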