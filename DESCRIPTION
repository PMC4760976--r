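Package: arcticpico
Title: Biogeography and Photosynthetic Biomass of Arctic Marine
    Pico-Eukaryotes from Fingerprints, Amplicons and Hydrography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for Arctic pico-eukaryote community
    analysis: ARISA fragment quality control, triplicate consolidation
    and binning into presence/absence community profiles; Jaccard
    distances with non-metric multidimensional scaling, Ward clustering,
    ANOSIM and Mantel permutation inference; a 454-style amplicon
    workflow (length/N/primer filtering, a two-parent chimera screen,
    farthest-neighbour OTU clustering at 97% identity, consensus calling,
    singleton removal) with bootstrapped k-mer taxonomy and abundant/rare
    biosphere partitioning; size-fractionated chlorophyll a bookkeeping;
    and water-mass oceanography (EOS-80 freezing line, density
    stratification, nitrate:phosphate Pacific-water fractions, Welch
    t-tests). A synthetic-data generator emulating water-mass-structured
    communities makes every stage testable without cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
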