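Package: shapesig
Title: Phenotype-Specific Signaling Network Inference from Expression and
    Cell Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives phenotype-specific signaling networks by integrating
    gene coexpression modules with cell-morphology features. Implements
    signed weighted coexpression analysis with topological overlap and
    permutation-corrected module-shape correlation, regulon and pathway
    enrichment with resampled-module null distributions, a randomized
    prize-collecting Steiner forest assembly with module and phenotype
    supernodes, semantic-similarity-weighted random walk with restart and
    empirical seed significance, drug-influence validation based on
    PageRank centrality and target overlap, and maximum-flow subnetwork
    extraction. A synthetic-data module generates all pipeline inputs with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
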