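`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded routines do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed below 2^31 from a master seed and integer keys.
derive_seed <- function(master, ...) {
  keys <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (k in keys) h <- (h * 1000003 + (k %% 1000000007)) %% 2147483629
  as.integer(h %% 2147483587 + 1)
}

# Polynomial content hash (mod a 25-bit prime, exact in doubles) of a
# character scalar or file.
content_hash <- function(x, is_file = FALSE) {
  if (is_file) x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  bytes <- utf8ToInt(x)
  if (length(bytes) == 0) return("0")
  h <- 0
  p <- 33554393
  # Horner in blocks keeps the R-level loop short
  block <- 4096L
  pow31 <- numeric(block)
  pow31[1] <- 1
  for (i in 2:block) pow31[i] <- (pow31[i - 1] * 31) %% p
  for (start in seq(1, length(bytes), by = block)) {
    chunk <- bytes[start:min(start + block - 1L, length(bytes))]
    n <- length(chunk)
    h <- (h * prod_mod(31, n, p) + sum((chunk * pow31[n:1]) %% p) %% p) %% p
  }
  format(h)
}

# 31^n mod p by repeated squaring (doubles are exact below 2^53).
prod_mod <- function(base, expo, p) {
  r <- 1; b <- base %% p
  while (expo > 0) {
    if (expo %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    expo <- expo %/% 2
  }
  r
}

stop_guard <- function(msg, call. = FALSE) {
  stop(structure(class = c("gpmapcorr_guard", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_input <- function(msg) {
  stop(structure(class = c("gpmapcorr_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
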