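#' Polyomino tile set from a genotype string
#'
#' A genotype of length `4 * N_t` over the alphabet `0 .. N_c - 1` encodes
#' `N_t` square tiles, four interface labels per tile written clockwise from
#' north. Interface types interact in ordered odd-even pairs
#' (1-2, 3-4, 5-6 for `N_c = 8`); label 0 is inert, as is any odd label whose
#' even partner exceeds `N_c - 1` (label 7 for `N_c = 8`).
#'
#' @param genotype the tile-set genotype string.
#' @param N_c number of interface types (default 8).
#' @return an object of class `tile_set` with `N_t`, `N_c` and an
#'   `N_t x 4` integer `edges` matrix (columns N, E, S, W).
#' @export
tile_set <- function(genotype, N_c = 8L) {
  chars <- strsplit(genotype, "")[[1]]
  if (length(chars) %% 4L != 0L || length(chars) == 0L)
    stop_input("genotype length must be a positive multiple of 4")
  labs <- suppressWarnings(as.integer(chars))
  if (anyNA(labs) || any(labs < 0L) || any(labs >= N_c))
    stop_input(sprintf("interface labels must lie in 0..%d", N_c - 1L))
  N_t <- length(chars) %/% 4L
  edges <- matrix(labs, nrow = N_t, ncol = 4L, byrow = TRUE)
  structure(list(N_t = N_t, N_c = as.integer(N_c), edges = edges,
                 genotype = genotype),
            class = "tile_set")
}

# interacting partner of an interface label under the odd-even rule, or 0
interface_partner <- function(a, N_c) {
  ifelse(a >= 1L & a %% 2L == 1L & a + 1L <= N_c - 1L, a + 1L,
         ifelse(a >= 2L & a %% 2L == 0L, a - 1L, 0L))
}

interacts <- function(a, b, N_c) {
  a >= 1L & b >= 1L & interface_partner(a, N_c) == b
}

#' Assembly protocol configuration
#'
#' @param n_repeats assembly attempts per genotype used by the determinism
#'   check (>= 2).
#' @param size_cap occupied-cell count above which assembly is declared
#'   unbounded; defaults to `16 * N_t` at classification time.
#' @param max_stall consecutive rejected random placements before an
#'   exhaustive attachability scan decides halting exactly.
#' @param seed master seed; per-repeat streams are derived from
#'   (genotype, repeat, seed).
#' @return an object of class `assembly_config`.
#' @export
assembly_config <- function(n_repeats = 20L, size_cap = NULL,
                            max_stall = 50L, seed = 1L) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 2L) stop_input("n_repeats must be >= 2")
  structure(list(n_repeats = n_repeats, size_cap = size_cap,
                 max_stall = as.integer(max_stall), seed = as.integer(seed)),
            class = "assembly_config")
}

# canonical form of a set of occupied cells: translate min corner to origin,
# take the lexicographically minimal cell string over 4 rotations
# (reflections optional: oriented interfaces make mirror shapes distinct).
canonical_shape <- function(cells, reflections = FALSE) {
  rot <- function(m) cbind(m[, 2], -m[, 1])
  images <- list(cells)
  for (i in 1:3) images[[i + 1]] <- rot(images[[i]])
  if (reflections) {
    refl <- cbind(cells[, 1], -cells[, 2])
    images <- c(images, list(refl))
    for (i in 1:3) images[[length(images) + 1]] <- rot(images[[length(images)]])
  }
  min(vapply(images, function(m) {
    m[, 1] <- m[, 1] - min(m[, 1]); m[, 2] <- m[, 2] - min(m[, 2])
    ord <- order(m[, 1], m[, 2])
    paste(paste(m[ord, 1], m[ord, 2], sep = ","), collapse = ";")
  }, character(1)))
}

# absolute directions: 1=N(y+1), 2=E(x+1), 3=S(y-1), 4=W(x-1)
dir_offsets <- function() rbind(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))

# edge label of a tile of type `ty` with rotation `rot` (0..3 clockwise
# quarter-turns) facing absolute direction d (1..4)
facing_edge <- function(edges, ty, rot, d) edges[ty, ((d - 1L - rot) %% 4L) + 1L]

#' Run one stochastic lattice self-assembly
#'
#' Seeds the lattice with tile 1 in orientation 0 at the origin, then
#' repeatedly draws a uniformly random (frontier cell, tile type, orientation)
#' triple, accepting the placement iff at least one edge facing an occupied
#' neighbour forms an interacting pair with that neighbour's facing edge.
#' Assembly halts with the shape when an exhaustive scan finds no attachable
#' placement, or returns `"UNBOUNDED"` when the structure exceeds `size_cap`.
#'
#' @param tiles a [tile_set()].
#' @param config an [assembly_config()].
#' @param reflections treat mirror shapes as identical (default `FALSE`).
#' @return canonical shape string, or `"UNBOUNDED"`.
#' @export
assemble_once <- function(tiles, config, reflections = FALSE) {
  N_c <- tiles$N_c
  edges <- tiles$edges
  size_cap <- config$size_cap %||% (16L * tiles$N_t)
  offs <- dir_offsets()
  occ <- new.env(parent = emptyenv())   # "x,y" -> c(type, rot)
  cells <- matrix(c(0L, 0L), ncol = 2)
  occ[["0,0"]] <- c(1L, 0L)
  frontier <- offs                       # cells adjacent to the seed
  fkeys <- apply(frontier, 1, paste, collapse = ",")
  can_attach <- function(cell, ty, rot) {
    for (d in 1:4) {
      nb <- cell + offs[d, ]
      nbv <- occ[[paste(nb, collapse = ",")]]
      if (is.null(nbv)) next
      mine <- facing_edge(edges, ty, rot, d)
      theirs <- facing_edge(edges, nbv[1], nbv[2], ((d + 1L) %% 4L) + 1L)
      if (interacts(mine, theirs, N_c)) return(TRUE)
    }
    FALSE
  }
  place <- function(cell, ty, rot) {
    key <- paste(cell, collapse = ",")
    occ[[key]] <- c(ty, rot)
    cells <<- rbind(cells, cell)
    for (d in 1:4) {
      nb <- cell + offs[d, ]
      nkey <- paste(nb, collapse = ",")
      if (is.null(occ[[nkey]]) && !(nkey %in% fkeys)) {
        frontier <<- rbind(frontier, nb)
        fkeys <<- c(fkeys, nkey)
      }
    }
    drop <- fkeys == key
    frontier <<- frontier[!drop, , drop = FALSE]
    fkeys <<- fkeys[!drop]
  }
  stalls <- 0L
  repeat {
    i <- sample.int(nrow(frontier), 1L)
    ty <- sample.int(tiles$N_t, 1L)
    rot <- sample.int(4L, 1L) - 1L
    if (can_attach(frontier[i, ], ty, rot)) {
      place(frontier[i, ], ty, rot)
      stalls <- 0L
      if (nrow(cells) > size_cap) return("UNBOUNDED")
    } else {
      stalls <- stalls + 1L
      if (stalls >= config$max_stall) {
        any_open <- FALSE
        for (fi in seq_len(nrow(frontier))) {
          for (ty2 in seq_len(tiles$N_t)) for (rot2 in 0:3) {
            if (can_attach(frontier[fi, ], ty2, rot2)) { any_open <- TRUE; break }
          }
          if (any_open) break
        }
        if (!any_open)
          return(canonical_shape(cells, reflections = reflections))
        stalls <- 0L
      }
    }
  }
}

#' Classify a tile-set genotype into a shape phenotype or UND
#'
#' Runs [assemble_once()] `n_repeats` times with independent RNG streams
#' derived from (genotype, repeat index, master seed). The genotype maps to
#' the shape label iff all repeats produce one identical bounded canonical
#' shape; any unbounded run or any pair of distinct shapes yields the
#' undefined phenotype `"UND"` (the deleterious label of this engine).
#'
#' @inheritParams assemble_once
#' @param und_label label for nondeterministic or unbounded assembly.
#' @return a phenotype label.
#' @export
classify_polyomino <- function(tiles, config = assembly_config(),
                               reflections = FALSE, und_label = "UND") {
  gkey <- sum(utf8ToInt(tiles$genotype) * seq_len(nchar(tiles$genotype)))
  first <- NULL
  for (rep in seq_len(config$n_repeats)) {
    s <- derive_seed(config$seed, gkey, rep)
    shape <- with_seed(s, assemble_once(tiles, config, reflections))
    if (identical(shape, "UNBOUNDED")) return(und_label)
    if (is.null(first)) first <- shape
    else if (!identical(shape, first)) return(und_label)
  }
  first
}

#' Build a polyomino GP map
#'
#' Complete table when `N_c^(4 N_t)` is small enough to enumerate; otherwise
#' a sampled-mode map wrapping the classification oracle.
#'
#' @param N_t number of tile types.
#' @param N_c number of interface types.
#' @param config an [assembly_config()].
#' @param reflections treat mirror shapes as identical.
#' @param guard maximum genotype count for complete enumeration.
#' @param override lift the guard.
#' @return a `gp_map` (complete or sampled) with del label `"UND"`.
#' @export
build_polyomino_map <- function(N_t, N_c = 8L, config = assembly_config(),
                                reflections = FALSE, guard = 2^20,
                                override = FALSE) {
  space <- genotype_space(N_c, 4L * N_t, polyomino_alphabet(N_c))
  oracle <- function(gs)
    vapply(gs, function(g) classify_polyomino(tile_set(g, N_c), config,
                                              reflections), character(1),
           USE.NAMES = FALSE)
  if (space$N_G <= guard || override) {
    if (space$N_G > 2^26)
      stop_guard("complete polyomino enumeration beyond 2^26 genotypes is refused")
    gs <- rank_to_genotype(seq_len(space$N_G) - 1, space)
    labs <- oracle(gs)
    labels <- sort(unique(labs))
    gp_map_complete(space, match(labs, labels), labels,
                    del_label = if ("UND" %in% labels) "UND" else NULL)
  } else {
    gp_map_sampled(space, oracle, del_label = "UND")
  }
}

#' Export shapes as TSV
#'
#' One line per phenotype: `shape_id<TAB>cells`, cells as semicolon-separated
#' `x,y` pairs in canonical orientation.
#'
#' @param shapes character vector of canonical shape strings.
#' @param path output path.
#' @export
write_shape_set <- function(shapes, path) {
  df <- data.frame(shape_id = shapes, cells = shapes)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
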