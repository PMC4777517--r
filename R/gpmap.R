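#' Construct a complete GP map
#'
#' A complete GP map stores one phenotype label per genotype, as an integer
#' code vector indexed by genotype rank (see [genotype_rank()]) with a
#' sidecar label table.
#'
#' @param space a [genotype_space()].
#' @param codes integer vector of length `N_G` with 1-based indices into
#'   `labels`.
#' @param labels character vector of phenotype labels.
#' @param del_label the designated deleterious phenotype label, or `NULL`.
#' @return an object of class `gp_map` with `mode = "complete"`.
#' @export
gp_map_complete <- function(space, codes, labels, del_label = NULL) {
  stopifnot(inherits(space, "genotype_space"))
  if (length(codes) != space$N_G)
    stop_input("complete map needs exactly N_G = K^L phenotype entries")
  codes <- as.integer(codes)
  if (anyNA(codes) || any(codes < 1L) || any(codes > length(labels)))
    stop_input("phenotype codes must index the label table")
  if (!is.null(del_label) && !del_label %in% labels)
    stop_input("del_label not among phenotype labels")
  structure(list(space = space, mode = "complete", codes = codes,
                 labels = labels, del_label = del_label),
            class = "gp_map")
}

#' Construct a sampled-mode GP map around a phenotype oracle
#'
#' For genotype spaces too large to enumerate, the map wraps a deterministic
#' oracle: a function taking a character vector of genotypes and returning
#' their phenotype labels. Queries are memoised, so repeated lookups of one
#' genotype are free and reproducibility of the oracle is observable.
#'
#' @param space a [genotype_space()].
#' @param oracle `function(genotypes) -> labels`.
#' @param del_label deleterious label, or `NULL`.
#' @return an object of class `gp_map` with `mode = "sampled"`.
#' @export
gp_map_sampled <- function(space, oracle, del_label = NULL) {
  stopifnot(inherits(space, "genotype_space"), is.function(oracle))
  structure(list(space = space, mode = "sampled", oracle = oracle,
                 del_label = del_label, memo = new.env(parent = emptyenv())),
            class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  cat(sprintf("gp_map (%s): K = %d, L = %d, N_G = %s\n", x$mode,
              x$space$K, x$space$L, format(x$space$N_G, big.mark = ",")))
  if (x$mode == "complete")
    cat(sprintf("phenotypes: %d%s\n", length(x$labels),
                if (!is.null(x$del_label))
                  sprintf(" (del = '%s')", x$del_label) else ""))
  invisible(x)
}

#' Phenotype labels of genotypes, by rank or by string
#'
#' @param map a `gp_map`.
#' @param ranks numeric vector of 0-based genotype ranks.
#' @param g character vector of genotype strings.
#' @return character vector of labels (`map_phenotype`) or integer codes
#'   (`map_codes`, complete mode only).
#' @export
map_phenotype <- function(map, g = NULL, ranks = NULL) {
  if (is.null(ranks)) ranks <- genotype_rank(g, map$space)
  if (map$mode == "complete") return(map$labels[map$codes[ranks + 1]])
  if (is.null(g)) g <- rank_to_genotype(ranks, map$space)
  key <- format(ranks, scientific = FALSE, trim = TRUE)
  known <- vapply(key, exists, logical(1), envir = map$memo)
  if (any(!known)) {
    ask <- !duplicated(key) & !known
    fresh <- map$oracle(g[ask])
    for (i in seq_along(which(ask)))
      assign(key[ask][i], fresh[i], envir = map$memo)
  }
  vapply(key, get, character(1), envir = map$memo, USE.NAMES = FALSE)
}

#' @rdname map_phenotype
#' @export
map_codes <- function(map, ranks) {
  if (map$mode != "complete")
    stop_input("map_codes requires a complete-mode map")
  map$codes[ranks + 1]
}

# ---- phenotype tables -------------------------------------------------------

#' Build a phenotype table from counts
#'
#' @param counts named numeric vector of redundancies `F_p` (each >= 1).
#' @param del_label deleterious label, or `NULL`.
#' @param N_G optional total genotype count; defaults to `sum(counts)`.
#' @return a data frame of class `phenotype_table` with columns `phenotype`,
#'   `count`, `frequency`, and attributes `N_P`, `N_G`, `del_label`.
#' @export
phenotype_table <- function(counts, del_label = NULL, N_G = NULL) {
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop_input("counts must be a named vector of redundancies")
  if (any(counts < 1)) stop_input("all redundancies F_p must be >= 1")
  N_G <- N_G %||% sum(counts)
  if (abs(sum(counts) - N_G) > 1e-9)
    stop_input("redundancies must sum to N_G")
  tab <- data.frame(phenotype = names(counts),
                    count = as.numeric(counts),
                    frequency = as.numeric(counts) / N_G,
                    stringsAsFactors = FALSE)
  attr(tab, "N_P") <- nrow(tab)
  attr(tab, "N_G") <- N_G
  attr(tab, "del_label") <- del_label
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Tabulate phenotype redundancies and frequencies of a complete map
#'
#' Counts every genotype exactly once; frequencies sum to 1.
#'
#' @param map a complete-mode `gp_map`.
#' @return a [phenotype_table()].
#' @export
tabulate_phenotypes <- function(map) {
  if (map$mode != "complete")
    stop_input("tabulate_phenotypes requires a complete-mode map; use estimate_frequencies for sampled maps")
  counts <- tabulate(map$codes, nbins = length(map$labels))
  keep <- counts > 0
  phenotype_table(stats::setNames(as.numeric(counts[keep]), map$labels[keep]),
                  del_label = map$del_label, N_G = map$space$N_G)
}

#' Monte-Carlo phenotype frequency estimates for sampled-mode maps
#'
#' Draws genotypes uniformly at random and reports per-phenotype frequency
#' estimates with binomial standard errors `sqrt(f(1-f)/n)`.
#'
#' @param map a `gp_map` (either mode).
#' @param n_samples number of uniform genotype draws.
#' @param seed integer seed.
#' @return a data frame with columns `phenotype`, `count`, `frequency`, `se`.
#' @export
estimate_frequencies <- function(map, n_samples, seed = 1) {
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  ranks <- with_seed(seed, floor(runif(n_samples) * map$space$N_G))
  labs <- map_phenotype(map, ranks = ranks)
  counts <- table(labs)
  f <- as.numeric(counts) / n_samples
  data.frame(phenotype = names(counts), count = as.numeric(counts),
             frequency = f, se = sqrt(f * (1 - f) / n_samples),
             stringsAsFactors = FALSE)
}

#' Neutral set of a phenotype
#'
#' @param map a complete-mode `gp_map`.
#' @param p phenotype label.
#' @return numeric vector of 0-based genotype ranks mapping to `p`.
#' @export
neutral_set <- function(map, p) {
  if (map$mode != "complete")
    stop_input("neutral_set requires a complete-mode map")
  code <- match(p, map$labels)
  if (is.na(code)) stop_input(sprintf("unknown phenotype '%s'", p))
  which(map$codes == code) - 1
}

# ---- TSV interfaces ---------------------------------------------------------

#' Read and write GP map tables
#'
#' The on-disk format is a two-column TSV `genotype<TAB>phenotype` with a
#' header line, optionally gzip-compressed (`.gz` suffix). The reader
#' validates that all genotypes share one length and alphabet and that the
#' table is total over `K^L`.
#'
#' @param map a complete-mode `gp_map`.
#' @param path file path (`.tsv` or `.tsv.gz`).
#' @param space optional [genotype_space()]; inferred from the file if absent.
#' @param del_label deleterious label to attach on read.
#' @return `read_gp_map`: a `gp_map`; `write_gp_map`: the path, invisibly.
#' @export
write_gp_map <- function(map, path) {
  if (map$mode != "complete") stop_input("only complete maps can be written")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("genotype\tphenotype", con)
  g <- rank_to_genotype(seq_len(map$space$N_G) - 1, map$space)
  writeLines(paste(g, map$labels[map$codes], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_gp_map
#' @export
read_gp_map <- function(path, space = NULL, del_label = NULL) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- tryCatch(read.delim(con, colClasses = "character"),
                 error = function(e) stop_input(paste("malformed map table:",
                                                      conditionMessage(e))))
  if (!identical(names(df), c("genotype", "phenotype")))
    stop_input("map table must have header 'genotype<TAB>phenotype'")
  lens <- unique(nchar(df$genotype))
  if (length(lens) != 1L) stop_input("genotypes must share one length")
  if (is.null(space)) {
    alpha <- sort(unique(unlist(strsplit(df$genotype, ""))))
    space <- genotype_space(length(alpha), lens, alpha)
  }
  if (nrow(df) != space$N_G)
    stop_input("map table must be total: expected K^L rows")
  r <- genotype_rank(df$genotype, space)
  if (anyDuplicated(r)) stop_input("duplicate genotypes in map table")
  labels <- sort(unique(df$phenotype))
  codes <- integer(space$N_G)
  codes[r + 1] <- match(df$phenotype, labels)
  gp_map_complete(space, codes, labels, del_label = del_label)
}

#' Write a phenotype table as TSV
#'
#' Columns `phenotype<TAB>count<TAB>frequency`.
#'
#' @param tab a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotype_table <- function(tab, path) {
  write.table(tab[, c("phenotype", "count", "frequency")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write a results table plus a JSON metadata sidecar (<path>.json) recording
# seeds, configuration and a content hash of the table itself.
write_result_tsv <- function(df, path, meta = list()) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta$content_hash <- content_hash(path, is_file = TRUE)
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
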