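test_that("tabulation counts every genotype once and normalises", {
  sp <- genotype_space(2, 1)
  m <- gp_map_complete(sp, c(1L, 2L), c("A", "B"))
  tab <- tabulate_phenotypes(m)
  expect_equal(tab$count, c(1, 1))
  expect_equal(tab$frequency, c(0.5, 0.5))

  m1 <- gp_map_complete(genotype_space(2, 4), rep(1L, 16), "only")
  tab1 <- tabulate_phenotypes(m1)
  expect_equal(attr(tab1, "N_P"), 1)
  expect_equal(tab1$frequency, 1)

  m2 <- make_random_map(3, 4, c(A = 20, B = 30, C = 31), seed = 2)
  expect_equal(sum(tabulate_phenotypes(m2)$frequency), 1, tolerance = 1e-12)
})

test_that("tabulation is invariant under genotype relabelling", {
  m <- make_random_map(2, 6, c(A = 10, B = 22, C = 32), seed = 4)
  # permute positions of every genotype: rebuild codes on permuted ranks
  sp <- m$space
  perm <- c(3, 1, 6, 2, 5, 4)
  gs <- all_genotypes(sp)
  permuted <- vapply(strsplit(gs, ""), function(ch)
    paste(ch[perm], collapse = ""), character(1))
  codes2 <- integer(sp$N_G)
  codes2[genotype_rank(permuted, sp) + 1] <- m$codes
  m2 <- gp_map_complete(sp, codes2, m$labels)
  t1 <- tabulate_phenotypes(m)
  t2 <- tabulate_phenotypes(m2)
  expect_equal(sort(t1$count), sort(t2$count))
})

test_that("frequency estimation is unbiased and converges to tabulation", {
  m <- make_random_map(2, 6, c(A = 32, B = 32), seed = 7)
  est <- estimate_frequencies(m, 10000, seed = 1)
  expect_true(all(abs(est$frequency - 0.5) < 3 * est$se))

  m1 <- gp_map_complete(genotype_space(2, 3), rep(1L, 8), "only")
  est1 <- estimate_frequencies(m1, 50, seed = 1)
  expect_equal(est1$frequency, 1)

  m2 <- make_random_map(2, 6, c(A = 8, B = 24, C = 32), seed = 3)
  tab <- tabulate_phenotypes(m2)
  est2 <- estimate_frequencies(m2, 20000, seed = 5)
  for (i in seq_len(nrow(tab))) {
    row <- est2[est2$phenotype == tab$phenotype[i], ]
    expect_true(abs(row$frequency - tab$frequency[i]) < 3 * row$se + 1e-9)
  }
})

test_that("sampled-mode maps memoise a deterministic oracle", {
  sp <- genotype_space(2, 5)
  calls <- new.env(); calls$n <- 0L
  oracle <- function(gs) {
    calls$n <- calls$n + length(gs)
    ifelse(substr(gs, 1, 1) == "0", "zero", "one")
  }
  m <- gp_map_sampled(sp, oracle, del_label = "zero")
  r <- c(0, 1, 17, 0, 1)
  lab1 <- map_phenotype(m, ranks = r)
  n_after_first <- calls$n
  lab2 <- map_phenotype(m, ranks = r)
  expect_identical(lab1, lab2)
  expect_equal(calls$n, n_after_first)        # memo hit: no new oracle calls
  expect_equal(n_after_first, 3)              # unique genotypes only
  expect_error(tabulate_phenotypes(m), "complete")
  expect_error(neutral_set(m, "zero"), "complete")
})

test_that("map TSV round-trips and rejects malformed tables", {
  m <- make_random_map(2, 5, c(A = 12, B = 20), seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_gp_map(m, path)
  m2 <- read_gp_map(path, del_label = NULL)
  ranks <- 0:(m$space$N_G - 1)
  expect_identical(map_phenotype(m2, ranks = ranks),
                   map_phenotype(m, ranks = ranks))
  # gzip round-trip
  pgz <- tempfile(fileext = ".tsv.gz")
  write_gp_map(m, pgz)
  expect_equal(tabulate_phenotypes(read_gp_map(pgz))$count,
               tabulate_phenotypes(m)$count)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("genotype\tphenotype", "00\tA", "000\tB"), bad)
  expect_error(read_gp_map(bad), class = "gpmapcorr_input")
  writeLines(c("g\tp", "00\tA"), bad)
  expect_error(read_gp_map(bad), class = "gpmapcorr_input")
  expect_error(read_gp_map(tempfile()), class = "gpmapcorr_input")
})

test_that("phenotype tables validate their invariants", {
  expect_error(phenotype_table(c(A = 0.5, B = 1)), "F_p")
  expect_error(phenotype_table(c(A = 3, B = 1), N_G = 8), "sum")
  tab <- phenotype_table(c(valid = 4175, invalid = 456976 - 4175),
                         del_label = "invalid")
  expect_equal(attr(tab, "N_G"), 456976)
  expect_equal(sum(tab$frequency), 1)
})

test_that("neutral sets contain exactly the matching genotypes", {
  m <- make_random_map(2, 5, c(A = 5, B = 27), seed = 1)
  ns <- neutral_set(m, "A")
  expect_length(ns, 5)
  expect_true(all(map_phenotype(m, ranks = ns) == "A"))
  expect_error(neutral_set(m, "C"), "unknown")
})
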