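# Neutral-neighbour counts n_{p,g} for every genotype of a complete map:
# one pass over the (K-1)L neighbour classes, fully vectorised.
neutral_neighbour_counts <- function(map) {
  space <- map$space
  r <- seq_len(space$N_G) - 1
  counts <- integer(space$N_G)
  K <- space$K; L <- space$L
  for (pos in seq_len(L)) {
    P <- as.numeric(K)^(L - pos)
    d <- (r %/% P) %% K
    for (j in seq_len(K - 1L)) {
      nb <- r + (((d + j) %% K) - d) * P
      counts <- counts + (map$codes[nb + 1] == map$codes)
    }
  }
  counts
}

#' Phenotype robustness
#'
#' The robustness of a phenotype is the mean fraction of the `(K-1) L`
#' one-mutation neighbours of its genotypes that share the phenotype,
#' averaged over the whole neutral set (exact mode) or over a uniform sample
#' of it (sampled mode, with standard errors). In the random null map this
#' equals the phenotype frequency, which is reported as the `null` column.
#'
#' @param map a `gp_map`.
#' @param p phenotype label(s); default all (complete mode).
#' @param mode `"exact"` (complete maps) or `"sampled"`.
#' @param sample_size genotypes drawn per phenotype in sampled mode.
#' @param seed integer seed (sampled mode).
#' @param keep_counts return the per-genotype neutral-neighbour counts.
#' @return a data frame with columns `phenotype`, `rho`, `null` (`= f_p`
#'   when available), and `se` in sampled mode.
#' @export
robustness <- function(map, p = NULL, mode = c("exact", "sampled"),
                       sample_size = 100L, seed = 1L, keep_counts = FALSE) {
  mode <- match.arg(mode)
  nn <- map$space$n_neighbours
  if (mode == "exact") {
    if (map$mode != "complete")
      stop_input("exact robustness requires a complete-mode map")
    counts <- neutral_neighbour_counts(map)
    tab <- tabulate_phenotypes(map)
    rho_all <- vapply(seq_along(map$labels), function(code) {
      sel <- map$codes == code
      if (!any(sel)) return(NA_real_)
      mean(counts[sel]) / nn
    }, numeric(1))
    out <- data.frame(phenotype = map$labels, rho = rho_all,
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$rho), ]
    out$null <- tab$frequency[match(out$phenotype, tab$phenotype)]
    if (!is.null(p)) {
      if (!all(p %in% out$phenotype)) stop_input("empty or unknown phenotype")
      out <- out[match(p, out$phenotype), ]
    }
    rownames(out) <- NULL
    if (keep_counts) attr(out, "n_pg") <- counts
    out
  } else {
    if (is.null(p)) stop_input("sampled robustness needs explicit phenotypes")
    rows <- lapply(p, function(ph) {
      g <- sample_neutral_set(map, ph, sample_size, seed = derive_seed(seed, match(ph, p)))
      fr <- vapply(g, function(r) {
        labs <- map_phenotype(map, ranks = neighbour_rank_matrix(r, map$space)[1, ])
        mean(labs == ph)
      }, numeric(1))
      data.frame(phenotype = ph, rho = mean(fr),
                 se = sd(fr) / sqrt(length(fr)), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Uniform-ish samples from a neutral set
#'
#' Complete maps sample uniformly from the stored neutral set. Sampled-mode
#' maps use uniform genotype draws filtered to the phenotype when hits are
#' frequent, and otherwise fall back to a neutral random walk from the first
#' genotype found, with a burn-in of `10 L` accepted neutral steps between
#' records (approximately uniform; the bias of walk sampling towards
#' high-robustness genotypes is documented).
#'
#' @param map a `gp_map`.
#' @param p phenotype label.
#' @param n number of draws.
#' @param seed integer seed.
#' @param max_tries attempt budget for the filtered search.
#' @return numeric vector of 0-based genotype ranks.
#' @export
sample_neutral_set <- function(map, p, n, seed = 1L, max_tries = 20000L) {
  n <- as.integer(n)
  if (map$mode == "complete") {
    members <- neutral_set(map, p)
    if (length(members) == 0L) stop_input("empty neutral set")
    return(with_seed(seed, members[sample.int(length(members), n, replace = TRUE)]))
  }
  with_seed(seed, {
    draws <- floor(runif(min(max_tries, 4L * n)) * map$space$N_G)
    hits <- draws[map_phenotype(map, ranks = draws) == p]
    if (length(hits) >= n) return(hits[seq_len(n)])
    # rare phenotype: neutral random walk from a found member
    start <- if (length(hits) > 0L) hits[1] else {
      more <- floor(runif(max_tries) * map$space$N_G)
      cand <- more[map_phenotype(map, ranks = more) == p]
      if (length(cand) == 0L)
        stop_input(sprintf("could not locate phenotype '%s' by uniform search", p))
      cand[1]
    }
    burn <- 10L * map$space$L
    out <- numeric(n)
    cur <- start
    accepted <- 0L
    total <- 0L
    while (total < n) {
      nbr <- neighbour_rank_matrix(cur, map$space)[1, ]
      nbr <- nbr[sample.int(length(nbr))]
      moved <- FALSE
      for (cand in nbr) {
        if (map_phenotype(map, ranks = cand) == p) {
          cur <- cand; moved <- TRUE; break
        }
      }
      if (!moved) { # isolated genotype: record it and restart from start
        out[total + 1L] <- cur; total <- total + 1L; cur <- start; next
      }
      accepted <- accepted + 1L
      if (accepted %% burn == 0L) { out[total + 1L] <- cur; total <- total + 1L }
    }
    out
  })
}

#' n-robustness curve and neutral correlation length
#'
#' The n-robustness of a phenotype is the mean fraction of its genotypes'
#' exact Hamming-distance-`n` mutants (shell size `choose(L,n) (K-1)^n`)
#' that share the phenotype. The curve is computed for `n = 1..n_max`; the
#' neutral correlation length `n_star` is the smallest `n` at which the
#' curve falls strictly below the null value `f_p` (NA when it never does).
#' Shells are enumerated exhaustively while `F_p_used x shell` stays below
#' `exact_bound`, otherwise genotypes and shell mutants are sampled.
#'
#' @param map a `gp_map`.
#' @param p phenotype label.
#' @param n_max largest radius (`<= L`).
#' @param genotype_sample genotypes sampled per radius when not exhaustive.
#' @param shell_sample shell draws per genotype when not exhaustive.
#' @param seed integer seed.
#' @param exact_bound work bound for exhaustive shell enumeration.
#' @param f_p null frequency; taken from the map's table when available.
#' @return a list of class `n_robustness_curve`: data frame `curve`
#'   (`n`, `rho_n`, `se`, `exact`), `null` (`f_p`), `n_star`.
#' @export
n_robustness <- function(map, p, n_max = NULL, genotype_sample = 100L,
                         shell_sample = 200L, seed = 1L,
                         exact_bound = 2e6, f_p = NULL) {
  space <- map$space
  n_max <- as.integer(n_max %||% space$L)
  if (n_max > space$L) stop_input("n_max must not exceed L")
  if (is.null(f_p)) {
    if (map$mode != "complete")
      stop_input("supply f_p for sampled-mode maps")
    tab <- tabulate_phenotypes(map)
    f_p <- tab$frequency[match(p, tab$phenotype)]
  }
  complete <- map$mode == "complete"
  members <- if (complete) neutral_set(map, p) else NULL
  rows <- lapply(seq_len(n_max), function(n) {
    shell <- shell_size(space, n)
    use_exact <- complete && length(members) * shell <= exact_bound
    if (use_exact) {
      fr <- vapply(members, function(r) {
        g <- rank_to_genotype(r, space)
        sh <- mutant_shell(g, n, space)
        mean(map_phenotype(map, g = sh) == p)
      }, numeric(1))
      data.frame(n = n, rho_n = mean(fr), se = 0, exact = TRUE)
    } else {
      gs <- if (complete)
        with_seed(derive_seed(seed, n, 1L),
                  members[sample.int(length(members), genotype_sample,
                                     replace = TRUE)])
      else sample_neutral_set(map, p, genotype_sample,
                              seed = derive_seed(seed, n, 1L))
      fr <- vapply(seq_along(gs), function(i) {
        g <- rank_to_genotype(gs[i], space)
        sh <- mutant_shell(g, n, space, sample_size = shell_sample,
                           seed = derive_seed(seed, n, 100L + i))
        mean(map_phenotype(map, g = sh) == p)
      }, numeric(1))
      data.frame(n = n, rho_n = mean(fr), se = sd(fr) / sqrt(length(fr)),
                 exact = FALSE)
    }
  })
  curve <- do.call(rbind, rows)
  below <- which(curve$rho_n < f_p)
  structure(list(phenotype = p, curve = curve, null = f_p,
                 n_star = if (length(below)) curve$n[below[1]] else NA_integer_),
            class = "n_robustness_curve")
}

#' Map-level average n-robustness
#'
#' Averages the per-phenotype n-robustness over all phenotypes (Eq-style
#' uniform phenotype average); the null value is `1/N_P` at every radius.
#' The map-level correlation length is the first radius where the average
#' falls strictly below `1/N_P`.
#'
#' @inheritParams n_robustness
#' @param phenotypes optional subset of phenotypes to average over.
#' @return a list: `curve` (`n`, `avg_rho_n`), `null` (`1/N_P`), `n_star`.
#' @export
avg_n_robustness <- function(map, n_max = NULL, phenotypes = NULL,
                             genotype_sample = 100L, shell_sample = 200L,
                             seed = 1L, exact_bound = 2e6) {
  tab <- tabulate_phenotypes(map)
  phenotypes <- phenotypes %||% tab$phenotype
  n_max <- as.integer(n_max %||% map$space$L)
  curves <- lapply(seq_along(phenotypes), function(i)
    n_robustness(map, phenotypes[i], n_max = n_max,
                 genotype_sample = genotype_sample,
                 shell_sample = shell_sample,
                 seed = derive_seed(seed, i), exact_bound = exact_bound))
  avg <- rowMeans(vapply(curves, function(cv) cv$curve$rho_n,
                         numeric(n_max)))
  null <- 1 / attr(tab, "N_P")
  below <- which(avg < null)
  list(curve = data.frame(n = seq_len(n_max), avg_rho_n = avg),
       null = null,
       n_star = if (length(below)) below[1] else NA_integer_,
       per_phenotype = curves)
}

#' Phenotype mutation probability matrix
#'
#' `phi[q, p]` is the probability that a random single mutation of a random
#' genotype of the neutral set of `p` yields phenotype `q`. Columns sum to 1
#' and the diagonal equals the phenotype robustness. Exact mode accumulates
#' all `N_G (K-1) L` directed neighbour pairs of a complete map; sampled
#' mode estimates columns from sampled neutral-set members.
#'
#' @param map a `gp_map`.
#' @param phenotypes column phenotypes `p` (default: all, complete mode).
#' @param mode `"exact"` or `"sampled"`.
#' @param sample_size genotypes per column in sampled mode.
#' @param seed integer seed.
#' @return an object of class `phi_matrix`: list with the `phi` matrix
#'   (rows `q`, columns `p`), `f` (global frequencies, exact mode), and
#'   helper columns from [phi_spearman()].
#' @export
phi_matrix <- function(map, phenotypes = NULL, mode = c("exact", "sampled"),
                       sample_size = 500L, seed = 1L) {
  mode <- match.arg(mode)
  space <- map$space
  if (mode == "exact") {
    if (map$mode != "complete")
      stop_input("exact phi matrix requires a complete-mode map")
    NP <- length(map$labels)
    acc <- numeric(NP * NP)
    r <- seq_len(space$N_G) - 1
    pcode <- map$codes
    K <- space$K; L <- space$L
    for (pos in seq_len(L)) {
      P <- as.numeric(K)^(L - pos)
      d <- (r %/% P) %% K
      for (j in seq_len(K - 1L)) {
        nb <- r + (((d + j) %% K) - d) * P
        qcode <- map$codes[nb + 1]
        acc <- acc + tabulate((pcode - 1L) * NP + qcode, nbins = NP * NP)
      }
    }
    phi <- matrix(acc, nrow = NP, ncol = NP,
                  dimnames = list(map$labels, map$labels))
    Fp <- tabulate(map$codes, nbins = NP)
    phi <- sweep(phi, 2, Fp * space$n_neighbours, "/")
    tab <- tabulate_phenotypes(map)
    if (!is.null(phenotypes)) phi <- phi[, phenotypes, drop = FALSE]
    structure(list(phi = phi,
                   f = stats::setNames(tab$frequency, tab$phenotype),
                   mode = "exact"),
              class = "phi_matrix")
  } else {
    if (is.null(phenotypes)) stop_input("sampled phi needs explicit phenotypes")
    cols <- lapply(seq_along(phenotypes), function(i) {
      p <- phenotypes[i]
      g <- sample_neutral_set(map, p, sample_size,
                              seed = derive_seed(seed, i))
      labs <- unlist(lapply(g, function(rr)
        map_phenotype(map, ranks = neighbour_rank_matrix(rr, space)[1, ])))
      prop.table(table(labs))
    })
    qlabs <- sort(unique(unlist(lapply(cols, names))))
    phi <- matrix(0, nrow = length(qlabs), ncol = length(phenotypes),
                  dimnames = list(qlabs, phenotypes))
    for (i in seq_along(cols)) phi[names(cols[[i]]), i] <- as.numeric(cols[[i]])
    structure(list(phi = phi, f = NULL, mode = "sampled",
                   sample_size = sample_size, seed = seed),
              class = "phi_matrix")
  }
}

#' Spearman correlation of a phi column with global frequency
#'
#' Rank correlation of `phi[q, p]` against `f_q` over the non-neutral
#' phenotypes `q != p` whose frequency exceeds the sampling threshold
#' `gamma = 1/(F_p (K-1) L)`. Phenotypes with `phi[q, p] = 0` (mutationally
#' unreachable from `p`) are flagged.
#'
#' @param pm a `phi_matrix` (exact mode).
#' @param map the complete map it came from.
#' @param p column phenotype.
#' @return a list with `spearman`, `n_used`, `unreachable` (labels with
#'   `phi = 0`), `gamma`.
#' @export
phi_spearman <- function(pm, map, p) {
  tab <- tabulate_phenotypes(map)
  Fp <- tab$count[match(p, tab$phenotype)]
  gamma <- percolation_thresholds(map$space$K, map$space$L, Fp)$gamma
  q <- setdiff(rownames(pm$phi), p)
  f_q <- pm$f[q]
  keep <- f_q > gamma
  phi_col <- pm$phi[q, p]
  list(spearman = if (sum(keep) >= 3)
         cor(phi_col[keep], f_q[keep], method = "spearman") else NA_real_,
       n_used = sum(keep),
       unreachable = q[phi_col == 0],
       gamma = gamma)
}

#' Bhattacharyya coefficient between two discrete distributions
#'
#' `sum_i sqrt(x_i y_i)` over the union of categories; 1 for identical
#' distributions, 0 for disjoint supports.
#'
#' @param x,y named probability vectors.
#' @return a number in `[0, 1]`.
#' @export
bhattacharyya <- function(x, y) {
  cats <- union(names(x), names(y))
  xv <- stats::setNames(numeric(length(cats)), cats); xv[names(x)] <- x
  yv <- stats::setNames(numeric(length(cats)), cats); yv[names(y)] <- y
  sum(sqrt(xv * yv))
}

#' Local over-representation of a phenotype in 1-mutation neighbourhoods
#'
#' Conditional distribution `P(q, p, m)` of the number of times `m` that
#' phenotype `q` occurs in the 1-mutation neighbourhood of a genotype of
#' phenotype `p`, given that it occurs at least once, with the conditioning
#' taken per neighbour slot (a uniformly chosen neighbour of a uniformly
#' chosen neutral-set member carries `q`) so that the random null map
#' reproduces the binomial null `P1` exactly. Averaged over a panel of `p`
#' phenotypes — by default the largest non-deleterious phenotypes other
#' than `q` — and compared with the binomial nulls from `f_q` (`P1`) and
#' `phi_qp` (`P2`).
#'
#' @param map a `gp_map`.
#' @param q the focal phenotype.
#' @param panel character vector of `p` phenotypes; default: the
#'   `panel_size` largest non-del phenotypes excluding `q`.
#' @param panel_size default panel size (10).
#' @param n_neigh_samples neighbourhoods sampled per panel phenotype
#'   (sampled mode; complete maps are computed exactly).
#' @param mode `"exact"` or `"sampled"`.
#' @param seed integer seed.
#' @return an object of class `overrep_distribution`: list with `m`
#'   (support `1..(K-1)L`), `P_bar`, `P1_bar`, `P2_bar`, their means,
#'   per-panel details, and `status` (`"ok"` or `"empty"`).
#' @export
overrep_distribution <- function(map, q, panel = NULL, panel_size = 10L,
                                 n_neigh_samples = 10000L,
                                 mode = c("exact", "sampled"), seed = 1L) {
  mode <- match.arg(mode)
  space <- map$space
  nn <- space$n_neighbours
  tab <- tabulate_phenotypes(map)
  if (!q %in% tab$phenotype) stop_input(sprintf("unknown phenotype '%s'", q))
  if (is.null(panel)) {
    cand <- tab[order(-tab$count), ]
    cand <- cand$phenotype[!(cand$phenotype %in% c(q, map$del_label))]
    panel <- head(cand, panel_size)
  }
  if (length(panel) == 0L) stop_input("empty phenotype panel")
  f_q <- tab$frequency[match(q, tab$phenotype)]
  qcode <- match(q, map$labels)
  m_support <- seq_len(nn)
  per <- lapply(seq_along(panel), function(i) {
    p <- panel[i]
    if (mode == "exact") {
      members <- neutral_set(map, p)
      counts <- rowSums(matrix(map$codes[neighbour_rank_matrix(members, space) + 1],
                               nrow = length(members)) == qcode)
      # slot-conditioned distribution: weight each genotype by its count m
      w <- tabulate(counts[counts > 0L], nbins = nn) * m_support
      phi_qp <- sum(counts) / (length(members) * nn)
      list(P = if (sum(w) > 0) w / sum(w) else rep(NA_real_, nn),
           phi_qp = phi_qp, n_cond = sum(counts > 0))
    } else {
      g <- sample_neutral_set(map, p, n_neigh_samples,
                              seed = derive_seed(seed, i))
      counts <- vapply(g, function(rr)
        sum(map_phenotype(map,
                          ranks = neighbour_rank_matrix(rr, space)[1, ]) == q),
        numeric(1))
      w <- tabulate(counts[counts > 0L], nbins = nn) * m_support
      phi_qp <- mean(counts) / nn
      list(P = if (sum(w) > 0) w / sum(w) else rep(NA_real_, nn),
           phi_qp = phi_qp, n_cond = sum(counts > 0))
    }
  })
  ok <- vapply(per, function(x) !anyNA(x$P), logical(1))
  if (!any(ok))
    return(structure(list(status = "empty", q = q, panel = panel),
                     class = "overrep_distribution"))
  P_bar <- rowMeans(vapply(per[ok], `[[`, numeric(nn), "P"))
  P1 <- null_overrep_P1(m_support, f_q, space$K, space$L)
  P2_bar <- rowMeans(vapply(per[ok], function(x)
    null_overrep_P2(m_support, x$phi_qp, space$K, space$L), numeric(nn)))
  structure(list(status = "ok", q = q, panel = panel[ok], m = m_support,
                 P_bar = P_bar, P1_bar = P1, P2_bar = P2_bar,
                 mean_m = sum(m_support * P_bar),
                 mean_m_P1 = sum(m_support * P1),
                 mean_m_P2 = sum(m_support * P2_bar),
                 phi_qp = vapply(per[ok], `[[`, numeric(1), "phi_qp"),
                 f_q = f_q),
            class = "overrep_distribution")
}

#' At-least-once probability and its null expectation
#'
#' Probability that phenotype `q` appears at least once in the 1-mutation
#' neighbourhood of a genotype of phenotype `p`, with the null expectation
#' `1 - (1 - phi_qp)^((K-1) L)`.
#'
#' @param map a complete-mode `gp_map`.
#' @param q,p phenotype labels.
#' @return list with `observed` and `null`.
#' @export
at_least_once <- function(map, q, p) {
  space <- map$space
  members <- neutral_set(map, p)
  qcode <- match(q, map$labels)
  counts <- rowSums(matrix(map$codes[neighbour_rank_matrix(members, space) + 1],
                           nrow = length(members)) == qcode)
  phi_qp <- sum(counts) / (length(members) * space$n_neighbours)
  list(observed = mean(counts > 0),
       null = 1 - (1 - phi_qp)^space$n_neighbours,
       phi_qp = phi_qp)
}

#' Mutational neighbourhood similarity of neutral neighbours
#'
#' For each draw: a genotype `g` is taken uniformly from the neutral set of
#' `p`, a neutral neighbour `h` uniformly among its neutral neighbours
#' (redrawing `g` when it has none), and a control genotype `g2` uniformly
#' from the neutral set excluding `g` and its neighbours. Local phenotype
#' distributions over the `(K-1) L` neighbour slots are compared with the
#' Bhattacharyya coefficient; for the `(g, h)` pair the `K - 2` mutual
#' neighbours (the other variants at the differing locus) are removed from
#' both distributions. The similarity ratio is `BC(g, h) / BC(g, g2)`.
#'
#' @param map a `gp_map`.
#' @param p phenotype label (needs `F_p >= 3`).
#' @param n_samples number of `(g, h, g2)` draws.
#' @param seed integer seed.
#' @param include_del include the deleterious phenotype as a category
#'   (default `TRUE`).
#' @return an object of class `similarity_sample`: list with `ratios`,
#'   `bc_gh`, `bc_gg2`, `mean_ratio` (finite ratios), `mean_ratio_positive`
#'   (draws with both coefficients positive), `se_ratio`, `status`.
#' @export
neighbourhood_similarity <- function(map, p, n_samples = 1000L, seed = 1L,
                                     include_del = TRUE) {
  space <- map$space
  K <- space$K; L <- space$L; nn <- space$n_neighbours
  if (map$mode != "complete")
    stop_input("neighbourhood similarity requires a complete-mode map")
  members <- neutral_set(map, p)
  if (length(members) < 3L) stop_input("phenotype needs F_p >= 3")
  pcode <- match(p, map$labels)
  del_code <- if (!include_del && !is.null(map$del_label))
    match(map$del_label, map$labels) else NA_integer_
  local_dist <- function(codes, drop_slots = NULL) {
    if (length(drop_slots)) codes <- codes[-drop_slots]
    if (!is.na(del_code)) codes <- codes[codes != del_code]
    if (length(codes) == 0L) return(stats::setNames(numeric(0), character(0)))
    tt <- tabulate(codes, nbins = length(map$labels))
    stats::setNames(tt[tt > 0] / sum(tt), map$labels[tt > 0])
  }
  with_seed(seed, {
    ratios <- numeric(n_samples)
    bc1 <- numeric(n_samples); bc2 <- numeric(n_samples)
    misses <- 0L
    for (s in seq_len(n_samples)) {
      # draw g until it has a neutral neighbour (redraw per the protocol)
      repeat {
        g <- members[sample.int(length(members), 1L)]
        g_nb <- neighbour_rank_matrix(g, space)[1, ]
        gcodes <- map$codes[g_nb + 1]
        hslots <- which(gcodes == pcode)
        if (length(hslots)) break
        misses <- misses + 1L
        if (misses > 200L && s == 1L)
          return(structure(list(status = "no-neutral-edges", phenotype = p),
                           class = "similarity_sample"))
      }
      hs <- hslots[sample.int(length(hslots), 1L)]
      h <- g_nb[hs]
      # differing locus: slot index -> position (slots are position-major)
      locus <- (hs - 1L) %/% (K - 1L) + 1L
      # control g2: a neutral non-neighbour distinct from g (rejection draw)
      g2 <- NA
      for (try in 1:200) {
        cand <- members[sample.int(length(members), 1L)]
        if (cand != g && !(cand %in% g_nb)) { g2 <- cand; break }
      }
      if (is.na(g2)) { ratios[s] <- NA; next }
      h_nb <- neighbour_rank_matrix(h, space)[1, ]
      hcodes <- map$codes[h_nb + 1]
      # mutual neighbours of g and h: the other variants at the differing
      # locus; their slots in each list, keeping h in g's and g in h's
      locus_slots <- ((locus - 1L) * (K - 1L) + 1L):(locus * (K - 1L))
      g_drop <- setdiff(locus_slots, hs)
      h_drop <- setdiff(locus_slots, locus_slots[h_nb[locus_slots] == g])
      x_g <- local_dist(gcodes, g_drop)
      x_h <- local_dist(hcodes, h_drop)
      g2codes <- map$codes[neighbour_rank_matrix(g2, space)[1, ] + 1]
      x_g_full <- local_dist(gcodes)
      x_g2 <- local_dist(g2codes)
      bc1[s] <- bhattacharyya(x_g, x_h)
      bc2[s] <- bhattacharyya(x_g_full, x_g2)
      ratios[s] <- if (bc2[s] > 0) bc1[s] / bc2[s] else NA_real_
    }
    fin <- is.finite(ratios)
    pos <- fin & bc1 > 0 & bc2 > 0
    structure(list(status = "ok", phenotype = p, ratios = ratios,
                   bc_gh = bc1, bc_gg2 = bc2,
                   mean_ratio = mean(ratios[fin]),
                   mean_ratio_positive = mean(ratios[pos]),
                   se_ratio = sd(ratios[fin]) / sqrt(sum(fin)),
                   n_used = sum(fin)),
              class = "similarity_sample")
  })
}

#' Deleterious-phenotype correlation ratios
#'
#' For each non-deleterious phenotype `p`, the ratio of the phenotype
#' mutation probability into the deleterious phenotype, `phi[del, p]`, to
#' its null expectation `f_del`; plus the self-ratio `rho_del / f_del`.
#' Ratios below 1 mean the deleterious phenotype is under-represented
#' around folding/assembling phenotypes.
#'
#' @param map a complete-mode `gp_map` with a del label.
#' @param panel optional subset of non-del phenotypes.
#' @return a list: data frame `ratios` (`phenotype`, `phi_del`, `ratio`),
#'   `mean_ratio`, `rho_del_over_f_del`, `f_del`.
#' @export
deleterious_correlation <- function(map, panel = NULL) {
  if (is.null(map$del_label)) stop_input("map has no deleterious phenotype")
  tab <- tabulate_phenotypes(map)
  f_del <- tab$frequency[match(map$del_label, tab$phenotype)]
  pm <- phi_matrix(map)
  pheno <- panel %||% setdiff(tab$phenotype, map$del_label)
  if (length(pheno) == 0L) stop_input("no non-deleterious phenotypes")
  phi_del <- pm$phi[map$del_label, pheno]
  rho_del <- pm$phi[map$del_label, map$del_label]
  list(ratios = data.frame(phenotype = pheno, phi_del = as.numeric(phi_del),
                           ratio = as.numeric(phi_del) / f_del,
                           stringsAsFactors = FALSE),
       mean_ratio = mean(phi_del / f_del),
       rho_del_over_f_del = rho_del / f_del,
       f_del = f_del)
}
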