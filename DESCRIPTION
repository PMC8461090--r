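Package: campart
Title: Phylogenetic-Bin Null Models for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the ecological processes driving microbial community
    turnover -- heterogeneous and homogeneous selection, homogenizing
    dispersal, dispersal limitation, and drift -- by combining phylogenetic
    binning with per-bin null models of the beta net relatedness index (bNRI)
    and the modified Raup-Crick index on Bray-Curtis dissimilarity. Includes
    rarefaction and count-table handling, alpha and beta diversity, PCoA and
    NMDS ordination, one-way PERMANOVA, and a simulator of membrane-biofilm
    style metacommunities with known ground-truth assembly regimes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
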