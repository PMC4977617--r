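Package: phenoprint
Title: Phenotypic Descriptor Diversity, Structure and Barcode Fingerprinting for Crop Landraces
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes crop landrace collections from qualitative (categorical)
    phenotypic descriptors. A trait catalogue drives one-hot ("phenoprint") encoding
    of genotype-by-trait state matrices; on top of that the package computes per-trait
    and per-group diversity statistics (observed and effective state numbers, Nei gene
    diversity, Shannon index, percent polymorphism, probability of identity), genotype
    and group genetic distances with neighbour-joining trees, one-level AMOVA with a
    permutation test of PhiST, Bayesian admixture-model clustering by Gibbs sampling
    with Evanno delta-K model choice, PCA-based trait-importance ranking, barcode
    (phenoprint) SVG rendering with duplicate detection, and greedy core-subset
    selection. A simulator generates synthetic panels with controlled categorical
    frequency, district and admixture structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
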