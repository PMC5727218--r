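Package: peascape
Title: Niche Modelling and Population-Genetic Analysis of Wild Pea Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated macroecology and population-genetics toolkit for
    crop wild relatives, exercised end-to-end on synthetic landscapes and
    genotypes. Provides a maximum-entropy presence-background niche model
    (fitting, AUC evaluation, permutation importance, projection onto
    alternative climate layer stacks), Schoener's D and Hellinger I niche
    overlap with a background-randomization similarity test, per-cell Shannon
    diversity maps over stacks of suitability surfaces, SNP quality control,
    per-individual heterozygosity, species-diagnostic SNP selection, Ritland
    kinship with distance-class spatial autocorrelation and permutation
    envelopes, pairwise Weir-Cockerham Fst, indel-aware haplotype collapsing
    and minimum-spanning haplotype networks, plus simulators that generate
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    geosphere,
    igraph,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
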