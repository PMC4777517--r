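#' Construct a genotype space
#'
#' A genotype space is the Hamming graph over all strings of length `L` drawn
#' from an ordered alphabet of `K` characters. It carries the alphabet, the
#' total genotype count `N_G = K^L`, and the per-genotype neighbour count
#' `(K-1)*L`.
#'
#' @param K alphabet size (integer >= 2).
#' @param L genotype length (integer >= 1).
#' @param alphabet optional character vector of `K` distinct single
#'   characters, in order. Defaults to digits then upper-case letters.
#' @return an object of class `genotype_space` with fields `K`, `L`,
#'   `alphabet`, `N_G` (stored as a double: spaces such as 8^12 exceed the
#'   32-bit integer range) and `n_neighbours`.
#' @examples
#' sp <- genotype_space(4, 12, rna_alphabet())
#' sp$N_G              # 16777216
#' sp$n_neighbours     # 36
#' @export
genotype_space <- function(K, L, alphabet = NULL) {
  K <- as.integer(K); L <- as.integer(L)
  if (is.na(K) || K < 2L) stop_input("K must be an integer >= 2")
  if (is.na(L) || L < 1L) stop_input("L must be an integer >= 1")
  if (is.null(alphabet)) alphabet <- default_alphabet(K)
  if (length(alphabet) == 1L && nchar(alphabet) > 1L)
    alphabet <- strsplit(alphabet, "")[[1]]
  if (length(alphabet) != K || anyDuplicated(alphabet) ||
      any(nchar(alphabet) != 1L))
    stop_input("alphabet must hold K distinct single characters")
  structure(list(K = K, L = L, alphabet = alphabet,
                 N_G = as.numeric(K)^L, n_neighbours = (K - 1L) * L),
            class = "genotype_space")
}

default_alphabet <- function(K) {
  pool <- c(as.character(0:9), LETTERS)
  if (K > length(pool)) stop_input("no default alphabet for K > 36")
  pool[seq_len(K)]
}

#' Canonical alphabets for the bundled GP-map engines
#'
#' @return character vector of single characters.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
rna_alphabet <- function() c("A", "U", "G", "C")

#' @rdname alphabets
#' @export
hp_alphabet <- function() c("H", "P")

#' @rdname alphabets
#' @export
polyomino_alphabet <- function(N_c = 8) as.character(seq_len(N_c) - 1L)

#' @rdname alphabets
#' @export
word_alphabet <- function() LETTERS

#' @export
print.genotype_space <- function(x, ...) {
  cat(sprintf("genotype space: K = %d, L = %d, N_G = %s, %d neighbours/genotype\n",
              x$K, x$L, format(x$N_G, big.mark = ","), x$n_neighbours))
  cat("alphabet:", paste(x$alphabet, collapse = ""), "\n")
  invisible(x)
}

# ---- rank <-> string coding -------------------------------------------------
# Genotypes are ranked in mixed radix with position 1 most significant,
# 0-based. Ranks are doubles (exact below 2^53).

letter_matrix <- function(g, space) {
  if (any(nchar(g) != space$L)) stop_input("genotype length must equal L")
  m <- matrix(match(unlist(strsplit(g, "")), space$alphabet),
              ncol = space$L, byrow = TRUE)
  if (anyNA(m)) stop_input("genotype contains characters outside the alphabet")
  m - 1L
}

#' Genotype rank and its inverse
#'
#' Complete maps index genotypes by their 0-based mixed-radix rank (position 1
#' most significant, letters in alphabet order).
#'
#' @param g character vector of genotype strings.
#' @param r numeric vector of 0-based ranks.
#' @param space a [genotype_space()].
#' @return `genotype_rank`: numeric ranks; `rank_to_genotype`: genotype strings.
#' @export
genotype_rank <- function(g, space) {
  m <- letter_matrix(g, space)
  pows <- as.numeric(space$K)^((space$L - 1):0)
  as.numeric(m %*% pows)
}

#' @rdname genotype_rank
#' @export
rank_to_genotype <- function(r, space) {
  if (any(r < 0 | r >= space$N_G)) stop_input("rank out of range")
  K <- space$K; L <- space$L
  out <- matrix("", nrow = length(r), ncol = L)
  rr <- as.numeric(r)
  for (pos in L:1) {
    d <- rr %% K
    out[, pos] <- space$alphabet[d + 1]
    rr <- (rr - d) / K
  }
  apply(out, 1, paste, collapse = "")
}

# digit of ranks at position pos (1-based, position 1 most significant)
rank_digit <- function(r, pos, space) {
  P <- as.numeric(space$K)^(space$L - pos)
  (r %/% P) %% space$K
}

# ---- neighbourhoods ---------------------------------------------------------

#' One-mutation neighbours of a genotype
#'
#' Returns the `(K-1)*L` genotypes at Hamming distance 1 from `g`, ordered
#' position-major with substituted letters in alphabet order.
#'
#' @param g a single genotype string.
#' @param space a [genotype_space()].
#' @return character vector of length `(K-1)*L`.
#' @examples
#' neighbours("00", genotype_space(2, 2))
#' @export
neighbours <- function(g, space) {
  stopifnot(length(g) == 1L)
  chars <- strsplit(g, "")[[1]]
  if (length(chars) != space$L) stop_input("genotype length must equal L")
  if (!all(chars %in% space$alphabet))
    stop_input("genotype contains characters outside the alphabet")
  out <- character(space$n_neighbours)
  k <- 1L
  for (pos in seq_len(space$L)) {
    for (a in space$alphabet) {
      if (a == chars[pos]) next
      mut <- chars; mut[pos] <- a
      out[k] <- paste(mut, collapse = ""); k <- k + 1L
    }
  }
  out
}

# All neighbour ranks of a rank vector, as a length(r) x (K-1)L matrix.
# Column order: position-major; within a position the K-1 alternatives are
# taken cyclically from each genotype's own digit ((d+j) mod K, j = 1..K-1),
# so every column is a valid neighbour slot for every row. Statistics only
# need the per-position multiset; the string-level neighbours() fixes the
# user-facing canonical order.
neighbour_rank_matrix <- function(r, space) {
  K <- space$K; L <- space$L
  out <- matrix(0, nrow = length(r), ncol = (K - 1L) * L)
  col <- 1L
  for (pos in seq_len(L)) {
    P <- as.numeric(K)^(L - pos)
    d <- (r %/% P) %% K
    for (j in seq_len(K - 1L)) {
      out[, col] <- r + (((d + j) %% K) - d) * P
      col <- col + 1L
    }
  }
  out
}

#' Exact-radius mutant shell of a genotype
#'
#' All genotypes at Hamming distance exactly `n` from `g` (shell size
#' `choose(L, n) * (K-1)^n`), or a uniform sample of the shell.
#'
#' @param g a single genotype string.
#' @param n shell radius, `1 <= n <= L`.
#' @param space a [genotype_space()].
#' @param sample_size `"all"` for full enumeration, or a positive integer
#'   number of independent uniform draws from the shell (with replacement).
#' @param seed integer seed used when sampling.
#' @return character vector of genotypes.
#' @examples
#' mutant_shell("000", 2, genotype_space(2, 3))
#' @export
mutant_shell <- function(g, n, space, sample_size = "all", seed = 1) {
  stopifnot(length(g) == 1L)
  n <- as.integer(n)
  if (n < 1L || n > space$L) stop_input("shell radius n must satisfy 1 <= n <= L")
  chars <- strsplit(g, "")[[1]]
  if (length(chars) != space$L) stop_input("genotype length must equal L")
  if (!all(chars %in% space$alphabet))
    stop_input("genotype contains characters outside the alphabet")
  K <- space$K
  if (identical(sample_size, "all")) {
    pos_sets <- combn(space$L, n)
    out <- character(0)
    alt <- lapply(seq_len(space$L), function(p) setdiff(space$alphabet, chars[p]))
    for (ci in seq_len(ncol(pos_sets))) {
      positions <- pos_sets[, ci]
      grids <- expand.grid(alt[positions], stringsAsFactors = FALSE)
      muts <- matrix(rep(chars, nrow(grids)), nrow = nrow(grids), byrow = TRUE)
      for (ii in seq_along(positions)) muts[, positions[ii]] <- grids[[ii]]
      out <- c(out, apply(muts, 1, paste, collapse = ""))
    }
    out
  } else {
    m <- as.integer(sample_size)
    stopifnot(m >= 1L)
    with_seed(seed, {
      vapply(seq_len(m), function(i) {
        positions <- sample.int(space$L, n)
        mut <- chars
        for (p in positions) mut[p] <- sample(setdiff(space$alphabet, chars[p]), 1L)
        paste(mut, collapse = "")
      }, character(1))
    })
  }
}

#' Size of the exact-radius mutant shell
#'
#' @param space a [genotype_space()].
#' @param n radius.
#' @return `choose(L, n) * (K-1)^n` as a double.
#' @export
shell_size <- function(space, n) {
  choose(space$L, n) * as.numeric(space$K - 1)^n
}
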