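Package: minihic
Title: Chromosome Structure Analysis for Small Circular Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing the three-dimensional organisation of small
    circular bacterial chromosomes from Hi-C contact data. Builds and filters
    binned contact matrices, balances them by iterative correction (ICE),
    reconstructs restraint-based 3D model ensembles by Monte Carlo simulated
    annealing, detects chromosome interaction domains (CIDs) with a
    BIC-penalised Poisson change-point segmentation over a power-law distance
    decay, tests genomic features at domain borders with circular-shift
    permutation tests, and relates domain structure to gene co-expression with
    a pairwise concordance (tendency) statistic. Ships a synthetic-data
    generator that emulates a genome-reduced bacterium (circular ~816 kb
    genome) so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
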