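Package: shrubphylo
Title: Phylogenetic Structure and Composition of Two-Habitat Shrub Communities
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Community-phylogenetics pipeline for site-by-species incidence
    data on a rooted, branch-lengthed phylogeny: Faith's phylogenetic
    diversity, mean pairwise and nearest-taxon distances, net relatedness and
    nearest taxon indices (NRI/NTI) under a richness-preserving species-pool
    null model, phylogenetic fuzzy weighting with principal coordinates of
    phylogenetic structure (PCPS), habitat contrasts (Wilcoxon, one-sample t,
    Pearson correlation) and three-predictor variation partitioning of
    phylogenetic diversity. Includes megatree pruning with genus-level
    grafting, a synthetic two-habitat data generator with tunable phylogenetic
    clustering/overdispersion, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
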