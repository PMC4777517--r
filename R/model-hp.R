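#' HP lattice model configuration
#'
#' Chains of hydrophobic (H) and polar (P) residues on the square lattice,
#' with contact energies `E_HH = -1`, `E_HP = E_PP = 0`. Folds are
#' self-avoiding walks; in compact mode they are restricted to Hamiltonian
#' paths of a `W x W` grid (so `L = W^2`), emulating maximally compact
#' globular proteins.
#'
#' @param L chain length (non-compact mode).
#' @param mode `"noncompact"` or `"compact"`.
#' @param W grid side for compact mode (`L` is then `W^2`).
#' @return an object of class `hp_config`.
#' @export
hp_config <- function(L = NULL, mode = c("noncompact", "compact"), W = NULL) {
  mode <- match.arg(mode)
  if (mode == "compact") {
    if (is.null(W)) stop_input("compact mode requires the grid side W")
    W <- as.integer(W)
    if (!is.null(L) && L != W^2)
      stop_input("compact mode requires L = W^2")
    L <- W^2L
  } else {
    if (is.null(L)) stop_input("non-compact mode requires the chain length L")
    L <- as.integer(L)
    W <- NA_integer_
  }
  structure(list(L = L, mode = mode, W = W,
                 E_HH = -1L, E_HP = 0L, E_PP = 0L),
            class = "hp_config")
}

# ---- fold geometry ----------------------------------------------------------

# The 8-element dihedral group of the square lattice, as 2x2 matrices.
d4_ops <- function() {
  rots <- list(matrix(c(1, 0, 0, 1), 2), matrix(c(0, -1, 1, 0), 2),
               matrix(c(-1, 0, 0, -1), 2), matrix(c(0, 1, -1, 0), 2))
  refl <- matrix(c(1, 0, 0, -1), 2)
  c(rots, lapply(rots, function(R) R %*% refl))
}

coords_key <- function(xy) {
  xy[, 1] <- xy[, 1] - min(xy[, 1])
  xy[, 2] <- xy[, 2] - min(xy[, 2])
  paste(paste(xy[, 1], xy[, 2], sep = ","), collapse = ";")
}

# Canonical id: lexicographically minimal coordinate string over the dihedral
# images, after translating the minimum corner to the origin. Chain direction
# is fixed (residue 1 stays residue 1).
canonical_fold_id <- function(xy, ops = d4_ops()) {
  min(vapply(ops, function(R) coords_key(xy %*% t(R)), character(1)))
}

fold_contacts <- function(xy) {
  L <- nrow(xy)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(L - 2L)) {
    for (j in seq(i + 2L, L)) {
      if (abs(xy[i, 1] - xy[j, 1]) + abs(xy[i, 2] - xy[j, 2]) == 1L)
        pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

new_fold <- function(xy) {
  id <- canonical_fold_id(xy)
  structure(list(coords = xy, contacts = fold_contacts(xy), id = id),
            class = "hp_fold")
}

#' Enumerate symmetry-distinct folds
#'
#' Depth-first enumeration of self-avoiding walks (non-compact mode) or of
#' Hamiltonian paths of the `W x W` grid (compact mode), reduced to one
#' representative per equivalence class under translation plus the dihedral
#' symmetry group of the lattice (4 rotations x reflection), with chain
#' direction fixed.
#'
#' @param config an [hp_config()].
#' @param override set `TRUE` to lift the non-compact length guard (`L <= 20`).
#' @return a list of `hp_fold` objects, each with fields `coords` (an `L x 2`
#'   integer matrix), `contacts` (pairs `i < j` of chain-non-adjacent,
#'   lattice-adjacent residues) and the canonical `id`.
#' @export
enumerate_folds <- function(config, override = FALSE) {
  stopifnot(inherits(config, "hp_config"))
  L <- config$L
  if (config$mode == "noncompact" && L > 20L && !override)
    stop_guard("non-compact fold enumeration beyond L = 20 must be explicitly overridden (override = TRUE)")
  seen <- new.env(parent = emptyenv())
  folds <- list()
  dirs <- rbind(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))
  in_box <- if (config$mode == "compact") {
    W <- config$W
    function(p) p[1] >= 1L && p[1] <= W && p[2] >= 1L && p[2] <= W
  } else function(p) TRUE
  record <- function(xy) {
    f <- new_fold(xy)
    if (!exists(f$id, envir = seen)) {
      assign(f$id, TRUE, envir = seen)
      folds[[length(folds) + 1L]] <<- f
    }
  }
  walk <- function(path, occupied) {
    step <- nrow(path)
    if (step == L) { record(path); return(invisible()) }
    for (k in 1:4) {
      nxt <- path[step, ] + dirs[k, ]
      key <- paste(nxt, collapse = ",")
      if (!in_box(nxt) || !is.null(occupied[[key]])) next
      occupied[[key]] <- TRUE
      walk(rbind(path, nxt), occupied)
      occupied[[key]] <- NULL
    }
  }
  starts <- if (config$mode == "compact") {
    W <- config$W
    as.matrix(expand.grid(x = 1:W, y = 1:W))
  } else matrix(c(0L, 0L), ncol = 2)
  for (s in seq_len(nrow(starts))) {
    p0 <- matrix(as.integer(starts[s, ]), ncol = 2)
    occ <- new.env(parent = emptyenv())
    occ[[paste(p0[1, ], collapse = ",")]] <- TRUE
    walk(p0, occ)
  }
  folds
}

#' Contact energy of a sequence threaded onto a fold
#'
#' `-1` per contact pair whose residues are both H; all other contacts
#' contribute 0.
#'
#' @param seq an HP string of length `L`.
#' @param fold an `hp_fold`.
#' @return integer energy `<= 0`.
#' @export
fold_energy <- function(seq, fold) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) != nrow(fold$coords))
    stop_input("sequence length must match the fold length")
  if (!all(chars %in% c("H", "P")))
    stop_input("sequence must be over the HP alphabet")
  if (nrow(fold$contacts) == 0L) return(0L)
  h <- chars == "H"
  -sum(h[fold$contacts[, 1]] & h[fold$contacts[, 2]])
}

#' Ground-state phenotype of an HP sequence
#'
#' The phenotype is the canonical id of the unique minimum-energy fold; if
#' two or more symmetry-distinct folds attain the minimum the sequence is
#' considered not to fold and is assigned the deleterious label.
#'
#' @param seq an HP string.
#' @param folds list of `hp_fold` (from [enumerate_folds()]).
#' @param del_label label for non-folding sequences.
#' @return a phenotype label.
#' @export
assign_hp_phenotype <- function(seq, folds, del_label = "del") {
  stopifnot(length(folds) >= 1L)
  e <- vapply(folds, function(f) fold_energy(seq, f), integer(1))
  mn <- min(e)
  hits <- which(e == mn)
  if (length(hits) > 1L) del_label else folds[[hits]]$id
}

# Energies of all sequences (rows of h, a 0/1 hydrophobicity matrix) on one
# fold, vectorised over sequences.
hp_energies_matrix <- function(h, fold) {
  if (nrow(fold$contacts) == 0L) return(numeric(nrow(h)))
  e <- numeric(nrow(h))
  for (k in seq_len(nrow(fold$contacts)))
    e <- e - h[, fold$contacts[k, 1]] * h[, fold$contacts[k, 2]]
  e
}

#' Build the complete HP GP map
#'
#' Assigns all `2^L` sequences their ground-state fold phenotype or the
#' deleterious label. Energy evaluation is vectorised over sequences and
#' processed in chunks to bound memory.
#'
#' @param config an [hp_config()].
#' @param del_label deleterious label.
#' @param guard_L refuse enumeration beyond this length (default 25).
#' @param override lift both guards.
#' @param chunk_size sequences per processing chunk.
#' @return a complete-mode `gp_map` over the alphabet `H`, `P`. Fold ids that
#'   are never a unique minimum are absent from the label set.
#' @export
build_hp_map <- function(config, del_label = "del", guard_L = 25L,
                         override = FALSE, chunk_size = 65536L) {
  if (config$L > guard_L && !override)
    stop_guard(sprintf("2^%d sequences exceed the enumeration guard; pass override = TRUE to force", config$L))
  folds <- enumerate_folds(config, override = override)
  space <- genotype_space(2L, config$L, hp_alphabet())
  ids <- vapply(folds, `[[`, character(1), "id")
  N <- space$N_G
  pheno <- integer(N)       # index into c(del_label, ids)
  for (start in seq(0, N - 1, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, N - 1)
    # alphabet is c("H","P"): digit 0 = H
    h <- matrix(0L, nrow = length(idx), ncol = config$L)
    for (pos in seq_len(config$L))
      h[, pos] <- as.integer(rank_digit(idx, pos, space) == 0)
    E <- vapply(folds, function(f) hp_energies_matrix(h, f),
                numeric(length(idx)))
    if (is.null(dim(E))) E <- matrix(E, nrow = 1L)
    mn <- do.call(pmin, as.data.frame(E))
    n_min <- rowSums(E == mn)
    arg <- max.col(-(E - mn), ties.method = "first")
    pheno[idx + 1] <- ifelse(n_min > 1L, 0L, arg)
  }
  used <- sort(unique(pheno[pheno > 0L]))
  labels <- c(del_label, ids[used])
  codes <- ifelse(pheno == 0L, 1L, match(pheno, used) + 1L)
  if (!any(pheno == 0L)) {       # no degenerate sequence at all
    labels <- ids[used]
    codes <- match(pheno, used)
  }
  gp_map_complete(space, codes, labels,
                  del_label = if (any(pheno == 0L)) del_label else NULL)
}

#' Export a fold set as TSV
#'
#' One row per fold: `fold_id<TAB>coords`, coordinates as semicolon-separated
#' `x,y` pairs with the minimum corner at the origin.
#'
#' @param folds list of `hp_fold`.
#' @param path output path.
#' @export
write_fold_set <- function(folds, path) {
  df <- data.frame(fold_id = vapply(folds, `[[`, character(1), "id"),
                   coords = vapply(folds, function(f) coords_key(f$coords),
                                   character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
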