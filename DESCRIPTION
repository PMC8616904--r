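Package: supergene
Title: Detection and Simulation of Chromosomal Inversion Supergenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for locating and characterising chromosomal inversion
    supergenes in diploid genotype data and for exploring the conditions
    that maintain them as balanced polymorphisms. Provides windowed
    diversity and differentiation scans (pi, dXY, Hudson FST), linkage
    disequilibrium decay curves, PCA plus heterozygosity based inversion
    genotyping, a latitude-cline test, ABBA-BABA D statistics with block
    jackknife significance, gene-tree topology weighting, a synthetic
    cohort generator for end-to-end validation, and two spatially
    explicit forward-time models of inversion polymorphism maintenance
    under selection, assortative mating, and migration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    phytools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
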