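Package: nemafun
Title: Soil Nematode Community Indices, Metabolic Footprints, and
    Ecosystem Multifunctionality
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of soil nematode communities as bioindicators of
    ecosystem function. Computes per-sample ecological and functional
    indices (Shannon, Simpson dominance, trophic diversity, Margalef
    richness, free-living maturity index, plant-parasite index, channel
    ratio, Wasilewska index), trophic-group metabolic footprints with
    enrichment/structure footprints and the faunal profile (enrichment
    and structure indices with quadrant diagnosis), min-max standardized
    ecosystem-multifunctionality scoring of soil carbon, nitrogen and
    phosphorus indicators, and the supporting community statistics
    (Bray-Curtis dissimilarity, ANOSIM and Mantel permutation tests,
    one-way ANOVA with LSD letters, genus-overlap partitions,
    correlation co-occurrence networks). A seeded synthetic community
    generator emulates a four-treatment, four-replicate grassland
    disturbance design for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
biocViews: Software, Metagenomics, Ecology
RoxygenNote: 7.3.3
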