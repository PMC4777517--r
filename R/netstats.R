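#' Neutral components of a phenotype
#'
#' Decomposes the neutral set `G_p` into its connected components under
#' neutral point mutations (Hamming-1 edges within `G_p`), using union-find
#' with union-by-size and path halving. Edges are enumerated position-major,
#' so the result is deterministic. Only complete-mode maps are supported:
#' component analysis requires the full neutral set.
#'
#' @param map a complete-mode `gp_map`.
#' @param p phenotype label.
#' @return an object of class `component_decomposition`: a list with
#'   `phenotype`, `members` (0-based ranks), `component` (component index per
#'   member), `sizes` (decreasing), `n_components`, `largest`.
#' @export
neutral_components <- function(map, p) {
  if (map$mode != "complete")
    stop_input("neutral_components requires a complete-mode map")
  members <- neutral_set(map, p)          # 0-based ranks, sorted
  Fp <- length(members)
  if (Fp == 0L) stop_input(sprintf("unknown or empty phenotype '%s'", p))
  space <- map$space
  # membership index over the whole space: 0 = not in G_p
  midx <- integer(space$N_G)
  midx[members + 1] <- seq_len(Fp)
  parent <- seq_len(Fp)
  csize <- rep(1L, Fp)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]     # path halving
      x <- parent[x]
    }
    x
  }
  nb <- neighbour_rank_matrix(members, space)
  for (col in seq_len(ncol(nb))) {
    other <- midx[nb[, col] + 1]
    sel <- which(other > 0L & other > seq_len(Fp))   # each edge once
    for (i in sel) {
      ra <- find(i); rb <- find(other[i])
      if (ra != rb) {
        if (csize[ra] < csize[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
        parent[rb] <- ra
        csize[ra] <- csize[ra] + csize[rb]
      }
    }
  }
  roots <- vapply(seq_len(Fp), find, integer(1))
  comp <- match(roots, unique(roots))
  sizes <- sort(tabulate(comp), decreasing = TRUE)
  structure(list(phenotype = p, members = members, component = comp,
                 sizes = sizes, n_components = length(sizes),
                 largest = sizes[1]),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("phenotype '%s': %d genotypes in %d component(s), largest = %d\n",
              x$phenotype, length(x$members), x$n_components, x$largest))
  invisible(x)
}

#' Per-phenotype percolation summary
#'
#' One row per phenotype with its frequency, largest neutral component,
#' component count, and flags against the giant-component (`delta`) and
#' single-component (`lambda`) thresholds of the random null map.
#'
#' @param map a complete-mode `gp_map`.
#' @param table optional [phenotype_table()] (tabulated from `map` if absent).
#' @return a data frame with columns `phenotype`, `F_p`, `f_p`,
#'   `largest_component`, `n_components`, `above_delta`, `above_lambda`.
#' @export
percolation_summary <- function(map, table = NULL) {
  table <- table %||% tabulate_phenotypes(map)
  th <- percolation_thresholds(map$space$K, map$space$L)
  rows <- lapply(table$phenotype, function(p) {
    cd <- neutral_components(map, p)
    data.frame(phenotype = p,
               F_p = length(cd$members),
               f_p = length(cd$members) / map$space$N_G,
               largest_component = cd$largest,
               n_components = cd$n_components,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$above_delta <- out$f_p > th$delta
  out$above_lambda <- out$f_p > th$lambda
  out
}
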