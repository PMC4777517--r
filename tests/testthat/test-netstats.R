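test_that("component decomposition handles trivial neutral sets", {
  sp <- genotype_space(2, 2)
  codes <- c(1L, 2L, 2L, 1L)      # "00" and "11" -> A, Hamming distance 2
  m <- gp_map_complete(sp, codes, c("A", "B"))
  cd <- neutral_components(m, "A")
  expect_equal(cd$n_components, 2)
  expect_equal(cd$sizes, c(1, 1))

  whole <- gp_map_complete(genotype_space(3, 3), rep(1L, 27), "all")
  cdw <- neutral_components(whole, "all")
  expect_equal(cdw$n_components, 1)
  expect_equal(cdw$largest, 27)
})

test_that("union-find agrees with breadth-first search on random maps", {
  set.seed(77)
  for (rep in 1:30) {
    K <- sample(2:3, 1); L <- sample(3:5, 1)
    NG <- K^L
    n1 <- sample.int(NG - 1, 1)
    m <- make_random_map(K, L, c(A = n1, B = NG - n1), seed = rep)
    for (p in c("A", "B")) {
      cd <- neutral_components(m, p)
      expect_equal(cd$sizes, bfs_components(m, p),
                   info = sprintf("K=%d L=%d rep=%d p=%s", K, L, rep, p))
    }
  }
})

test_that("union-find agrees with igraph components", {
  skip_if_not_installed("igraph")
  m <- make_random_map(3, 4, c(A = 30, B = 51), seed = 5)
  members <- neutral_set(m, "A")
  nbm <- neighbour_rank_matrix(members, m$space)
  idx <- match(as.vector(nbm), members)
  edges <- cbind(rep(seq_along(members), ncol(nbm)), idx)
  edges <- edges[!is.na(edges[, 2]), , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(members) - igraph::vcount(g))
  ref <- sort(igraph::components(g)$csize, decreasing = TRUE)
  expect_equal(neutral_components(m, "A")$sizes, ref)
})

test_that("components are invariant under alphabet and position relabelling", {
  m <- make_random_map(2, 6, c(A = 14, B = 50), seed = 11)
  sp <- m$space
  gs <- all_genotypes(sp)
  # swap letters and permute positions
  swapped <- chartr("01", "10", gs)
  perm <- c(4, 6, 1, 3, 2, 5)
  permuted <- vapply(strsplit(swapped, ""), function(ch)
    paste(ch[perm], collapse = ""), character(1))
  codes2 <- integer(sp$N_G)
  codes2[genotype_rank(permuted, sp) + 1] <- m$codes
  m2 <- gp_map_complete(sp, codes2, m$labels)
  expect_equal(neutral_components(m2, "A")$sizes,
               neutral_components(m, "A")$sizes)
})

test_that("null maps form one component above lambda and fragment below delta", {
  sp <- genotype_space(4, 6)
  th <- percolation_thresholds(4, 6)
  # f = 0.5 > lambda ~ 0.37: a single component in (at least) 9/10 seeds
  single <- vapply(1:10, function(s) {
    m <- make_random_map(4, 6, c(big = 2048, rest = 2048), seed = 400 + s)
    neutral_components(m, "big")$n_components == 1
  }, logical(1))
  expect_gte(sum(single), 9)
  # f far below delta = 1/18: largest component is a vanishing part of F_p
  frac <- vapply(1:10, function(s) {
    m <- make_random_map(4, 6, c(tiny = 16, rest = 4080), seed = 500 + s)
    cd <- neutral_components(m, "tiny")
    cd$largest / 16
  }, numeric(1))
  expect_lt(mean(frac), 0.35)
})

test_that("below delta the component count scales with the neutral set size", {
  counts <- c(p1 = 8, p2 = 16, p3 = 32, p4 = 64, p5 = 128,
              rest = 4096 - 248)
  rho <- vapply(1:5, function(s) {
    m <- make_random_map(4, 6, counts, seed = 600 + s)
    ncomp <- vapply(paste0("p", 1:5), function(p)
      neutral_components(m, p)$n_components, numeric(1))
    cor(ncomp, counts[1:5], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.8)
})

test_that("a constructed Hamming-ball phenotype is one component below delta", {
  spec <- spectrum_spec(2, 10, counts = c(ball = 56, del = 968))
  m <- generate_correlated_map(spec, "hamming_ball", strength = 1, seed = 3)
  th <- percolation_thresholds(2, 10)
  expect_lt(56 / 1024, th$delta * 6)   # small-frequency regime
  cd <- neutral_components(m, "ball")
  expect_equal(cd$n_components, 1)
})

test_that("the percolation summary tabulates every phenotype with flags", {
  m <- make_random_map(2, 6, c(A = 40, B = 24), seed = 2)
  ps <- percolation_summary(m)
  expect_setequal(ps$phenotype, c("A", "B"))
  expect_equal(sum(ps$F_p), 64)
  expect_true(all(c("largest_component", "n_components",
                    "above_delta", "above_lambda") %in% names(ps)))
  expect_equal(ps$above_lambda, ps$f_p > percolation_thresholds(2, 6)$lambda)
})
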