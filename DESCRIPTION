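Package: ibdstruct
Title: Population Structure, Ancestry and Kinship from Identity-by-Descent Sharing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for ancient-DNA population-structure analysis built on
    pairwise identity-by-descent (IBD) segment sharing. Implements segment-level
    quality control with removal of excess-IBD regions, construction of
    genome-fraction sharing matrices, iterative hierarchical Leiden community
    detection on IBD-sharing networks, leave-one-out IBD painting with
    supervised non-negative least-squares ancestry modelling and weighted block
    jackknife standard errors, allele-frequency-free kinship classification
    (R0, R1, KING-robust), runs-of-homozygosity summaries with parental
    relatedness and uniparental disomy flags, and haplogroup calling from
    phylogenetic placement weights. Includes synthetic cohort generators with
    known truth so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
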