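# Independent oracles and small fixtures, built in code at test time.

# All genotype strings of a space (only for tiny spaces).
all_genotypes <- function(space) {
  rank_to_genotype(seq_len(space$N_G) - 1, space)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force mutant shell: filter the whole space by Hamming distance.
brute_shell <- function(g, n, space) {
  gs <- all_genotypes(space)
  gs[vapply(gs, hamming, numeric(1), a = g) == n]
}

# Breadth-first-search decomposition of a neutral set (oracle for union-find).
bfs_components <- function(map, p) {
  members <- neutral_set(map, p)
  space <- map$space
  memb <- new.env(parent = emptyenv())
  for (m in members) assign(format(m, scientific = FALSE), TRUE, envir = memb)
  seen <- new.env(parent = emptyenv())
  sizes <- integer(0)
  for (m in members) {
    key <- format(m, scientific = FALSE)
    if (exists(key, envir = seen)) next
    queue <- m
    assign(key, TRUE, envir = seen)
    size <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      for (nb in neighbour_rank_matrix(cur, space)[1, ]) {
        nk <- format(nb, scientific = FALSE)
        if (exists(nk, envir = memb) && !exists(nk, envir = seen)) {
          assign(nk, TRUE, envir = seen)
          queue <- c(queue, nb)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Exhaustive maximum base pairing with a loop constraint (oracle for the DP):
# recursive enumeration over nested pair sets.
brute_max_pairs <- function(seq, hairpin_min = 3,
                            pairs = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  chars <- strsplit(seq, "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% pairs
  rec <- function(i, j) {
    if (j - i < hairpin_min + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + hairpin_min + 1L):j) {
      if (ok(chars[i], chars[k])) {
        inner <- rec(i + 1L, k - 1L)
        rest <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, inner + 1L + rest)
      }
    }
    best
  }
  if (length(chars) < hairpin_min + 2) 0L else rec(1L, length(chars))
}

count_pairs_db <- function(db) sum(strsplit(db, "")[[1]] == "(")

# A small complete random map with the given named counts.
make_random_map <- function(K, L, counts, seed = 1, alphabet = NULL) {
  space <- genotype_space(K, L, alphabet)
  del <- if ("del" %in% names(counts)) "del" else NULL
  randomize_gp_map(phenotype_table(counts, del_label = del), space, seed = seed)
}
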