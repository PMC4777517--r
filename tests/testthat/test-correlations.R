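test_that("hand-checked robustness values are reproduced", {
  # G_A = {00, 01}: each member has one neutral neighbour of two
  sp <- genotype_space(2, 2)
  m <- gp_map_complete(sp, c(1L, 1L, 2L, 2L), c("A", "B"))
  rb <- robustness(m, "A")
  expect_equal(rb$rho, 0.5)
  # a phenotype covering the whole space is perfectly robust
  whole <- gp_map_complete(genotype_space(2, 4), rep(1L, 16), "all")
  expect_equal(robustness(whole)$rho, 1)
  # single-site map {0 -> A, 1 -> B}: phi_BA = 1, phi_AA = 0
  m1 <- gp_map_complete(genotype_space(2, 1), c(1L, 2L), c("A", "B"))
  pm <- phi_matrix(m1)
  expect_equal(pm$phi["B", "A"], 1)
  expect_equal(pm$phi["A", "A"], 0)
})

test_that("exact-mode identities hold on every complete map", {
  maps <- list(make_random_map(2, 6, c(A = 10, B = 22, C = 32), seed = 2),
               make_random_map(3, 4, c(A = 27, B = 54), seed = 5),
               build_rna_map(5),
               build_hp_map(hp_config(mode = "compact", W = 3)))
  for (m in maps) {
    rb <- robustness(m)
    pm <- phi_matrix(m)
    expect_equal(unname(colSums(pm$phi)), rep(1, ncol(pm$phi)),
                 tolerance = 1e-12)
    for (p in rb$phenotype) {
      expect_equal(pm$phi[p, p], rb$rho[rb$phenotype == p],
                   tolerance = 1e-12)
    }
    # rho^(1) from the shell formulation equals the direct robustness
    p1 <- rb$phenotype[1]
    nr <- n_robustness(m, p1, n_max = 1)
    expect_equal(nr$curve$rho_n[1], rb$rho[rb$phenotype == p1],
                 tolerance = 1e-12)
  }
})

test_that("sampled statistics converge to exact values on small maps", {
  m <- make_random_map(2, 6, c(A = 20, B = 44), seed = 8)
  exact <- robustness(m)
  for (p in c("A", "B")) {
    sm <- robustness(m, p, mode = "sampled", sample_size = 400, seed = 3)
    expect_lt(abs(sm$rho - exact$rho[exact$phenotype == p]),
              3 * sm$se + 1e-9)
  }
  pm_ex <- phi_matrix(m)
  pm_sm <- phi_matrix(m, phenotypes = "B", mode = "sampled",
                      sample_size = 600, seed = 4)
  for (q in rownames(pm_sm$phi)) {
    se <- sqrt(pm_ex$phi[q, "B"] * (1 - pm_ex$phi[q, "B"]) / (600 * 6))
    expect_lt(abs(pm_sm$phi[q, "B"] - pm_ex$phi[q, "B"]), 4 * se + 0.01)
  }
})

test_that("n-robustness is flat on null maps and decays on correlated maps", {
  # whole-space phenotype: rho^(n) = 1 for every n, no crossing
  whole <- gp_map_complete(genotype_space(2, 5), rep(1L, 32), "all")
  nr <- n_robustness(whole, "all", n_max = 5)
  expect_equal(nr$curve$rho_n, rep(1, 5))
  expect_true(is.na(nr$n_star))

  # random map: rho^(n) ~ f_p at every radius
  m <- make_random_map(2, 8, c(A = 128, B = 128), seed = 6)
  nr2 <- n_robustness(m, "A", n_max = 8)
  expect_lt(max(abs(nr2$curve$rho_n - 0.5)), 0.06)

  # Hamming-ball phenotype: decay from high robustness to below f_p
  spec <- spectrum_spec(2, 10, counts = c(ball = 56, del = 968))
  mb <- generate_correlated_map(spec, "hamming_ball", strength = 1, seed = 3)
  nrb <- n_robustness(mb, "ball", n_max = 10)
  f <- 56 / 1024
  expect_gt(nrb$curve$rho_n[1], 3 * f)
  expect_false(is.na(nrb$n_star))
  expect_gt(nrb$n_star, 1)
  expect_true(all(diff(nrb$curve$rho_n[1:4]) <= 0))
})

test_that("the map-level average n-robustness matches its null on random maps", {
  tab_counts <- c(A = 128, B = 64, C = 32, D = 32)
  m <- make_random_map(2, 8, tab_counts, seed = 13)
  av <- avg_n_robustness(m, n_max = 3)
  expect_equal(av$null, 0.25)
  expect_lt(max(abs(av$curve$avg_rho_n - rowMeans(
    vapply(av$per_phenotype, function(cv) rep(cv$null, 3), numeric(3))))),
    0.08)
})

test_that("phi columns track global frequency above the gamma threshold", {
  counts <- c(p1 = 1024, p2 = 512, p3 = 256, p4 = 1280, p5 = 1024)
  devs <- c()
  spear <- c()
  for (s in 1:6) {
    m <- make_random_map(4, 6, counts, seed = 700 + s)
    pm <- phi_matrix(m)
    sA <- phi_spearman(pm, m, "p1")
    spear <- c(spear, sA$spearman)
    for (q in setdiff(names(counts), "p1")) {
      f_q <- counts[q] / 4096
      se <- sqrt(f_q * (1 - f_q) / (counts["p1"] * 18))
      devs <- c(devs, (pm$phi[q, "p1"] - f_q) / se)
    }
  }
  expect_lt(mean(abs(devs) > 3), 0.15)
  expect_gt(mean(spear), 0.5)
})

test_that("local over-representation recovers its binomial null on random maps", {
  counts <- c(q = 512, p1 = 1792, p2 = 1792)
  tv <- c(); dm <- c()
  for (s in 1:5) {
    m <- make_random_map(4, 6, counts, seed = 800 + s)
    ov <- overrep_distribution(m, "q", panel = c("p1", "p2"))
    expect_equal(ov$status, "ok")
    expect_equal(sum(ov$P_bar), 1, tolerance = 1e-9)
    tv <- c(tv, 0.5 * sum(abs(ov$P_bar - ov$P1_bar)))
    dm <- c(dm, ov$mean_m - ov$mean_m_P1)
  }
  expect_lt(mean(tv), 0.05)
  expect_lt(abs(mean(dm)), 0.1)
})

test_that("a Hamming-ball phenotype is locally over-represented", {
  spec <- spectrum_spec(2, 10, counts = c(ball = 120, del = 904))
  mb <- generate_correlated_map(spec, "hamming_ball", strength = 1, seed = 9)
  ov <- overrep_distribution(mb, "ball", panel = "del")
  expect_gt(ov$mean_m, ov$mean_m_P1)
  expect_gt(ov$mean_m, ov$mean_m_P2)
})

test_that("the at-least-once identity holds on random maps", {
  m <- make_random_map(4, 6, c(q = 410, p = 1024, rest = 2662), seed = 10)
  alo <- at_least_once(m, "q", "p")
  expect_lt(abs(alo$observed - alo$null), 0.02)
})

test_that("neighbourhood similarity is 1 on fully neutral and null maps", {
  whole <- gp_map_complete(genotype_space(4, 4), rep(1L, 256), "all")
  ns <- neighbourhood_similarity(whole, "all", n_samples = 40, seed = 1)
  expect_equal(ns$mean_ratio, 1, tolerance = 1e-12)
  expect_equal(unique(ns$bc_gh), 1)

  m <- make_random_map(4, 6, c(A = 2048, B = 2048), seed = 15)
  nsr <- neighbourhood_similarity(m, "A", n_samples = 500, seed = 2)
  expect_lt(abs(nsr$mean_ratio - 1), 3 * nsr$se_ratio + 0.01)
})

test_that("locus-determined phenotypes have similar neutral-neighbour neighbourhoods", {
  spec <- spectrum_spec(2, 10, counts = c(A = 256, B = 768))
  ml <- generate_correlated_map(spec, "locus_block", strength = 1,
                                block_loci = 2, seed = 4)
  ns <- neighbourhood_similarity(ml, "B", n_samples = 800, seed = 2)
  expect_gt(ns$mean_ratio, 1 + 3 * ns$se_ratio)
  # both zero-handling conventions are reported
  expect_true(is.finite(ns$mean_ratio_positive))
})

test_that("similarity reports an explicit status for edgeless phenotypes", {
  sp <- genotype_space(2, 3)
  # phenotype at {000, 011, 101, 110}: pairwise Hamming distance 2
  codes <- rep(2L, 8)
  codes[genotype_rank(c("000", "011", "101", "110"), sp) + 1] <- 1L
  m <- gp_map_complete(sp, codes, c("even", "odd"))
  ns <- neighbourhood_similarity(m, "even", n_samples = 10, seed = 1)
  expect_equal(ns$status, "no-neutral-edges")
})

test_that("deleterious correlations are flat on null maps and negative on
           anti-correlated constructions", {
  ratios <- vapply(1:6, function(s) {
    m <- make_random_map(2, 8, c(fold = 64, del = 192), seed = 900 + s)
    deleterious_correlation(m)$mean_ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(6))

  # del occupying one hemisphere (first locus = 1): folded ratios < 1
  sp <- genotype_space(2, 10)
  r <- 0:(2^10 - 1)
  first <- gpmapcorr:::rank_digit(r, 1, sp)
  codes <- ifelse(first == 1, 2L, 1L)
  m2 <- gp_map_complete(sp, codes, c("fold", "del"), del_label = "del")
  dc <- deleterious_correlation(m2)
  expect_lt(dc$ratios$ratio[dc$ratios$phenotype == "fold"], 1)
  expect_gt(dc$rho_del_over_f_del, 1)
})

test_that("the compact HP map under-connects folded phenotypes to del", {
  m <- build_hp_map(hp_config(mode = "compact", W = 4))
  dc <- deleterious_correlation(m)
  expect_lt(dc$mean_ratio, 1)
  expect_gt(dc$rho_del_over_f_del, 1)
  m_nodel <- gp_map_complete(genotype_space(2, 3), rep(1L, 8), "all")
  expect_error(deleterious_correlation(m_nodel), "deleterious")
})
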