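#!/usr/bin/env Rscript
# Slow full-enumeration regressions (hours of CPU; not part of the default
# test run). Reproduces the headline counts of the two large complete maps:
#   * compact HP 5x5: number of folded phenotypes and deleterious fraction
#   * polyomino S_2,8: number of self-assembling shape phenotypes and UND
#     fraction (stochastic protocol; rerun with doubled repeats and cap to
#     check stability)
# Usage: Rscript scripts/regression-slow.R [hp5x5|s28] [--seed <int>]
suppressPackageStartupMessages(library(gpmapcorr))

args <- commandArgs(trailingOnly = TRUE)
what <- if (length(args) >= 1 && !grepl("^--", args[1])) args[1] else "hp5x5"
seed <- 1L
if ("--seed" %in% args) seed <- as.integer(args[which(args == "--seed") + 1L])

if (what == "hp5x5") {
  t0 <- Sys.time()
  map <- build_hp_map(hp_config(mode = "compact", W = 5), override = TRUE,
                      chunk_size = 262144L)
  tab <- tabulate_phenotypes(map)
  folded <- sum(tab$phenotype != "del")
  f_del <- tab$frequency[tab$phenotype == "del"]
  cat(sprintf("HP5x5: %d folded phenotypes, del fraction %.3f (%.1f min)\n",
              folded, f_del, as.numeric(difftime(Sys.time(), t0, units = "mins"))))
} else if (what == "s28") {
  t0 <- Sys.time()
  cfg <- assembly_config(n_repeats = 20, seed = seed)
  map <- build_polyomino_map(2, N_c = 8, config = cfg, override = TRUE)
  tab <- tabulate_phenotypes(map)
  shapes <- sum(tab$phenotype != "UND")
  f_und <- tab$frequency[tab$phenotype == "UND"]
  cat(sprintf("S_2,8: %d self-assembling phenotypes, UND fraction %.3f (%.1f min)\n",
              shapes, f_und, as.numeric(difftime(Sys.time(), t0, units = "mins"))))
} else stop("unknown target: ", what)
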