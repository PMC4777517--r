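#' Specify a phenotype frequency spectrum
#'
#' Either an explicit named vector of redundancies summing to `K^L`, or a
#' parametric spectrum: `n_phenotypes` frequencies drawn log-uniformly over
#' `decades` orders of magnitude, optionally topped up with a deleterious
#' phenotype of stated frequency. Realised counts are rounded to integers
#' (each at least 1) and the total repaired by adjusting the largest
#' phenotype, so the counts always sum to `K^L` exactly.
#'
#' @param K,L space dimensions.
#' @param counts explicit named redundancies (overrides the parametric form).
#' @param n_phenotypes number of non-deleterious phenotypes.
#' @param decades log-range of the parametric spectrum.
#' @param del_frequency frequency of the deleterious phenotype (0 for none).
#' @param alphabet optional alphabet forwarded to [genotype_space()].
#' @param seed integer seed for the parametric draw.
#' @return an object of class `spectrum_spec` with `space`, `counts`,
#'   `del_label`.
#' @export
spectrum_spec <- function(K, L, counts = NULL, n_phenotypes = 10L,
                          decades = 3, del_frequency = 0, alphabet = NULL,
                          seed = 1L) {
  space <- genotype_space(K, L, alphabet)
  if (is.null(counts)) {
    if (space$N_G > 2^28) stop_input("parametric spectra need an enumerable space")
    N <- space$N_G
    F_del <- round(del_frequency * N)
    avail <- N - F_del
    if (avail < n_phenotypes)
      stop_input("not enough genotypes for the requested spectrum")
    raw <- with_seed(seed, 10^runif(n_phenotypes, -decades, 0))
    F_p <- pmax(1, round(raw / sum(raw) * avail))
    F_p[which.max(F_p)] <- F_p[which.max(F_p)] + (avail - sum(F_p))
    if (any(F_p < 1)) stop_input("spectrum infeasible: a phenotype rounded to zero")
    counts <- stats::setNames(F_p, sprintf("p%02d", seq_len(n_phenotypes)))
    del_label <- NULL
    if (F_del > 0) { counts <- c(counts, del = F_del); del_label <- "del" }
  } else {
    if (abs(sum(counts) - space$N_G) > 1e-9)
      stop_input("explicit counts must sum to K^L")
    del_label <- if ("del" %in% names(counts)) "del" else NULL
  }
  structure(list(space = space, counts = counts, del_label = del_label),
            class = "spectrum_spec")
}

#' Generate an uncorrelated random GP map from a spectrum
#'
#' Delegates to [randomize_gp_map()] on the realised spectrum: phenotypes
#' are scattered uniformly over the genotype space, frequencies preserved
#' exactly. This is the null condition every correlation statistic is
#' compared against.
#'
#' @param spec a [spectrum_spec()].
#' @param seed integer seed.
#' @return a complete-mode `gp_map`.
#' @export
generate_random_map <- function(spec, seed = 1L) {
  tab <- phenotype_table(spec$counts, del_label = spec$del_label)
  randomize_gp_map(tab, spec$space, seed = seed)
}

#' Generate a positively correlated GP map (positive control)
#'
#' Produces maps whose phenotypes are clustered in genotype space, so that
#' robustness exceeds frequency by construction:
#' * `hamming_ball`: each phenotype grows from a random seed genotype by
#'   neutral accretion — with probability `strength` the next genotype is
#'   drawn from the cluster's unassigned Hamming-1 frontier, otherwise
#'   uniformly from the unassigned remainder — until its exact count is
#'   reached.
#' * `locus_block`: phenotypes are determined primarily by `block_loci`
#'   genomic positions: genotypes are ordered block-major (random within a
#'   block value) and sliced by cumulative count, then a fraction
#'   `1 - strength` of assignments is shuffled.
#'
#' Both modes preserve the requested spectrum exactly; `strength = 0` is
#' statistically indistinguishable from [generate_random_map()].
#'
#' @param spec a [spectrum_spec()].
#' @param clustering `"hamming_ball"` or `"locus_block"`.
#' @param strength clustering strength in `[0, 1]`.
#' @param block_loci number of determining loci (`locus_block`).
#' @param seed integer seed.
#' @return a complete-mode `gp_map`.
#' @export
generate_correlated_map <- function(spec, clustering = c("hamming_ball",
                                                         "locus_block"),
                                    strength = 1, block_loci = 2L, seed = 1L) {
  clustering <- match.arg(clustering)
  stopifnot(strength >= 0, strength <= 1)
  space <- spec$space
  N <- as.integer(space$N_G)
  counts <- spec$counts
  labels <- names(counts)
  codes <- integer(N)                      # 0 = unassigned
  if (clustering == "hamming_ball") {
    with_seed(seed, {
      # grow small phenotypes first so their clusters stay intact; the
      # largest (typically the deleterious background) absorbs the residue
      ord <- order(counts)
      for (ci in ord) {
        target <- counts[ci]
        frontier <- integer(0)
        placed <- 0
        while (placed < target) {
          frontier <- frontier[codes[frontier] == 0L]
          use_frontier <- length(frontier) > 0L && runif(1) < strength
          cell <- if (use_frontier) {
            i <- sample.int(length(frontier), 1L)
            cl <- frontier[i]; frontier <- frontier[-i]; cl
          } else {
            un <- which(codes == 0L)
            un[sample.int(length(un), 1L)]
          }
          if (codes[cell] != 0L) next
          codes[cell] <- ci
          placed <- placed + 1
          nbr <- neighbour_rank_matrix(cell - 1, space)[1, ] + 1
          frontier <- c(frontier, nbr[codes[nbr] == 0L])
        }
      }
    })
  } else {
    block_loci <- as.integer(block_loci)
    stopifnot(block_loci >= 1L, block_loci <= space$L)
    r <- seq_len(N) - 1
    K <- space$K
    block_val <- 0
    for (b in seq_len(block_loci))
      block_val <- block_val * K + rank_digit(r, b, space)
    with_seed(seed, {
      ord <- order(block_val, runif(N))
      codes[ord] <- rep.int(seq_along(counts), counts)
      n_swap <- round((1 - strength) * N)
      if (n_swap > 1) {
        sel <- sample.int(N, n_swap)
        codes[sel] <- codes[sel[sample.int(n_swap)]]
      }
    })
  }
  gp_map_complete(space, codes, labels, del_label = spec$del_label)
}

#' Build the 4-letter word-game GP map
#'
#' Maynard-Smith-style parlour game: over the `26^L` strings of upper-case
#' letters, the "valid" phenotype is membership in a supplied word list and
#' everything else is "invalid" (playing the deleterious role). Words are
#' case-folded; entries that are not purely alphabetic of length `L` are
#' ignored.
#'
#' @param word_list_path plain-text word list, one word per line. Defaults
#'   to the small demo list bundled with the package.
#' @param L word length (default 4).
#' @return a complete-mode `gp_map` over A-Z with labels `valid`/`invalid`.
#' @export
build_wordgame_map <- function(word_list_path = NULL, L = 4L) {
  word_list_path <- word_list_path %||%
    system.file("extdata", "words4_demo.txt", package = "gpmapcorr")
  if (!file.exists(word_list_path)) stop_input("word list file not found")
  words <- toupper(trimws(readLines(word_list_path, warn = FALSE)))
  words <- unique(words[grepl(sprintf("^[A-Z]{%d}$", L), words)])
  if (length(words) == 0L) stop_input("word list contains no valid words")
  space <- genotype_space(26L, L, word_alphabet())
  codes <- rep(2L, space$N_G)              # invalid
  codes[genotype_rank(words, space) + 1] <- 1L
  gp_map_complete(space, codes, c("valid", "invalid"), del_label = "invalid")
}

#' Summary statistics of a word-game map
#'
#' @param map a map from [build_wordgame_map()].
#' @return a list with `F_valid`, `f_valid`, `rho_valid`, and the component
#'   decomposition of the valid set.
#' @export
wordgame_summary <- function(map) {
  members <- neutral_set(map, "valid")
  nb <- neighbour_rank_matrix(members, map$space)
  neut <- matrix(map$codes[nb + 1] == 1L, nrow = length(members))
  cd <- neutral_components(map, "valid")
  list(F_valid = length(members),
       f_valid = length(members) / map$space$N_G,
       rho_valid = mean(rowSums(neut)) / map$space$n_neighbours,
       components = cd)
}
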