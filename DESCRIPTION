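Package: gpmapcorr
Title: Genetic Correlations in Genotype-Phenotype Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds genotype-phenotype (GP) maps from biophysically motivated
    lattice models (HP protein folding, polyomino self-assembly, a toy RNA
    secondary-structure folder) and from synthetic generators, and quantifies
    their genetic correlations against a frequency-matched random null map.
    Implements phenotype robustness and n-robustness with the neutral
    correlation length, neutral-component decomposition and percolation
    thresholds on Hamming graphs, phenotype mutation probability matrices,
    local over-representation statistics with binomial nulls, mutational
    neighbourhood similarity via Bhattacharyya coefficients, and
    deleterious-phenotype correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
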