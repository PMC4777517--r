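#' RNA folding configuration
#'
#' The built-in `toy` backend is a self-contained maximum-base-pairing
#' folder (dynamic programming with a minimum-loop constraint and a
#' deterministic traceback). It exists so every correlation statistic has a
#' fully reproducible RNA-like engine; it makes no claim to reproduce
#' thermodynamic folding. The `external` backend delegates to an `RNAfold`
#' executable on the PATH and parses its dot-bracket output.
#'
#' @param backend `"toy"` or `"external"`.
#' @param hairpin_min minimum number of unpaired bases in a hairpin loop
#'   (toy backend, default 3).
#' @param pairs character vector of allowed pairs.
#' @return an object of class `rna_config`.
#' @export
rna_config <- function(backend = c("toy", "external"), hairpin_min = 3L,
                       pairs = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  backend <- match.arg(backend)
  hairpin_min <- as.integer(hairpin_min)
  if (hairpin_min < 1L) stop_input("hairpin_min must be >= 1")
  alpha <- rna_alphabet()
  can_pair <- matrix(FALSE, 4, 4, dimnames = list(alpha, alpha))
  for (pr in pairs) can_pair[substr(pr, 1, 1), substr(pr, 2, 2)] <- TRUE
  structure(list(backend = backend, hairpin_min = hairpin_min,
                 can_pair = can_pair),
            class = "rna_config")
}

#' Fold RNA sequences into secondary structures
#'
#' @param seqs character vector of sequences over `AUGC`.
#' @param config an [rna_config()].
#' @return character vector of dot-bracket structures.
#' @examples
#' fold_rna("GGGGAAAACCCC", rna_config())
#' @export
fold_rna <- function(seqs, config = rna_config()) {
  m <- letter_matrix(seqs, genotype_space(4L, nchar(seqs[1]), rna_alphabet()))
  if (config$backend == "toy") {
    nussinov_db(m, config$hairpin_min, unname(config$can_pair))
  } else {
    exe <- Sys.which("RNAfold")
    if (exe == "") stop_input("external backend requires RNAfold on the PATH")
    out <- system2(exe, args = "--noPS", input = seqs, stdout = TRUE)
    db <- out[seq(2, length(out), by = 2)]
    vapply(strsplit(db, " "), `[[`, character(1), 1)
  }
}

#' Dot-bracket parsing and rendering
#'
#' @param db a dot-bracket string.
#' @param pairs a 2-column matrix of paired positions `(i, j)`, `i < j`.
#' @param L structure length.
#' @return `db_to_pairs`: the pair matrix; `pairs_to_db`: the string.
#' @export
db_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      if (length(open) == 0L) stop_input("unbalanced dot-bracket string")
      out <- rbind(out, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) stop_input("unbalanced dot-bracket string")
  out[order(out[, 1]), , drop = FALSE]
}

#' @rdname db_to_pairs
#' @export
pairs_to_db <- function(pairs, L) {
  chars <- rep(".", L)
  chars[pairs[, 1]] <- "("
  chars[pairs[, 2]] <- ")"
  paste(chars, collapse = "")
}

#' Build the complete toy-RNA GP map
#'
#' Phenotype labels are dot-bracket structures; the deleterious label is the
#' fully unpaired structure (the strand that does not fold).
#'
#' @param L sequence length.
#' @param config an [rna_config()].
#' @param guard_L refuse complete enumeration beyond this length (default 12).
#' @param override lift the guard.
#' @return a complete-mode `gp_map` over `AUGC`.
#' @export
build_rna_map <- function(L, config = rna_config(), guard_L = 12L,
                          override = FALSE) {
  L <- as.integer(L)
  if (L > guard_L && !override)
    stop_guard(sprintf("4^%d sequences exceed the enumeration guard; pass override = TRUE to force", L))
  space <- genotype_space(4L, L, rna_alphabet())
  codes_mat <- matrix(0L, nrow = space$N_G, ncol = L)
  idx <- seq_len(space$N_G) - 1
  for (pos in seq_len(L))
    codes_mat[, pos] <- as.integer(rank_digit(idx, pos, space))
  db <- if (config$backend == "toy") {
    nussinov_db(codes_mat, config$hairpin_min, unname(config$can_pair))
  } else {
    fold_rna(rank_to_genotype(idx, space), config)
  }
  del <- strrep(".", L)
  labels <- sort(unique(c(db, del)))
  gp_map_complete(space, match(db, labels), labels, del_label = del)
}
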