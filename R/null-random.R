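#' Percolation thresholds of the random GP map
#'
#' Closed-form thresholds on the Hamming graph for a frequency-matched
#' random GP map:
#' * `delta = 1 / ((K-1) L)` — giant-component onset: phenotypes with
#'   frequency above `delta` are expected to form extended neutral networks
#'   (mean number of neutral neighbours reaches one);
#' * `lambda = 1 - (1/K)^(1/(K-1))` — single-component onset: above this
#'   frequency virtually the whole neutral set coalesces into one component;
#' * `gamma = 1 / (F_p (K-1) L)` — sampling threshold: phenotypes with
#'   frequency below `gamma` are expected to be absent from the 1-mutation
#'   neighbourhood of a neutral set of size `F_p`.
#'
#' @param K alphabet size.
#' @param L genotype length.
#' @param F_p optional neutral-set size for `gamma`.
#' @return a list with `delta`, `lambda`, and `gamma` (when `F_p` given).
#' @examples
#' percolation_thresholds(4, 12)$delta   # 1/36
#' percolation_thresholds(2, 10)$lambda  # 0.5
#' @export
percolation_thresholds <- function(K, L, F_p = NULL) {
  stopifnot(K >= 2, L >= 1)
  out <- list(delta = 1 / ((K - 1) * L),
              lambda = 1 - (1 / K)^(1 / (K - 1)))
  if (!is.null(F_p)) out$gamma <- 1 / (F_p * (K - 1) * L)
  out
}

#' Frequency-matched random (null) GP map
#'
#' Randomly assigns the `F_p` genotypes of each phenotype to the genotype
#' space: the rank array is shuffled with a seeded Fisher-Yates permutation
#' (R's `sample.int`) and sliced by cumulative redundancy, so the phenotype
#' frequency spectrum is preserved exactly while all arrangement structure
#' is destroyed.
#'
#' @param table a [phenotype_table()] whose counts sum to `K^L`.
#' @param space a [genotype_space()].
#' @param seed integer seed.
#' @return a complete-mode `gp_map`.
#' @export
randomize_gp_map <- function(table, space, seed = 1) {
  counts <- table$count
  if (abs(sum(counts) - space$N_G) > 1e-9)
    stop_input("phenotype counts must sum to K^L")
  if (space$N_G > 2^28)
    stop_guard("complete randomisation beyond 2^28 genotypes is refused")
  N <- as.integer(space$N_G)
  perm <- with_seed(seed, sample.int(N))
  codes <- integer(N)
  codes[perm] <- rep.int(seq_along(counts), counts)
  gp_map_complete(space, codes, table$phenotype,
                  del_label = attr(table, "del_label"))
}

#' Binomial null distributions for local over-representation
#'
#' Probability that a phenotype `q`, given present at one specific neighbour,
#' occurs `m` times in total in a 1-mutation neighbourhood of `(K-1) L`
#' genotypes: a binomial over the remaining `(K-1) L - 1` neighbours with
#' per-neighbour rate `f_q` (`P1`) or the map's phenotype mutation
#' probability `phi_qp` (`P2`).
#'
#' @param m occurrence count(s), `1 <= m <= (K-1) L`.
#' @param f_q global frequency of `q` (for `P1`).
#' @param phi_qp phenotype mutation probability (for `P2`).
#' @param K,L alphabet size and genotype length.
#' @return probability vector, summing to 1 over `m = 1..(K-1)L`.
#' @export
null_overrep_P1 <- function(m, f_q, K, L) {
  n <- (K - 1) * L
  if (any(m < 1 | m > n)) stop_input("m must lie in 1..(K-1)L")
  if (f_q < 0 || f_q > 1) stop_input("f_q must be a probability")
  dbinom(m - 1, n - 1, f_q)
}

#' @rdname null_overrep_P1
#' @export
null_overrep_P2 <- function(m, phi_qp, K, L) {
  n <- (K - 1) * L
  if (any(m < 1 | m > n)) stop_input("m must lie in 1..(K-1)L")
  if (phi_qp < 0 || phi_qp > 1) stop_input("phi_qp must be a probability")
  dbinom(m - 1, n - 1, phi_qp)
}

#' Analytic null robustness columns
#'
#' In the random GP map the phenotype robustness equals the frequency
#' (`rho_p = f_p`), the mean neutral-neighbour count is `(K-1) L f_p`, and
#' the average n-robustness over phenotypes is `1/N_P` at every radius.
#'
#' @param table a [phenotype_table()].
#' @param K,L optional space dimensions for the neighbour-count column.
#' @return a list with `rho_p` (named by phenotype), `avg_n_robustness`, and
#'   `mean_neutral_neighbours` when `K`, `L` are supplied.
#' @export
null_robustness <- function(table, K = NULL, L = NULL) {
  out <- list(rho_p = stats::setNames(table$frequency, table$phenotype),
              avg_n_robustness = 1 / attr(table, "N_P"))
  if (!is.null(K) && !is.null(L))
    out$mean_neutral_neighbours <-
      stats::setNames((K - 1) * L * table$frequency, table$phenotype)
  out
}
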