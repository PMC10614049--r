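# Internal helpers shared across modules.

#' Clip values into a closed interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Deterministic child seed derivation
#'
#' Expands one user seed into per-stage / per-replicate seeds so stages are
#' individually reproducible. Linear-congruential step keeps results in
#' [1, 2^31 - 2], valid for `set.seed()`.
#' @noRd
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

#' Evaluate an expression with a temporary RNG seed, restoring prior state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Standardize columns to zero mean / unit SD, dropping constants
#' @return list(x = matrix, kept = logical over input columns)
#' @noRd
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  kept <- is.finite(sdv) & sdv > 0
  z <- sweep(sweep(x[, kept, drop = FALSE], 2, mu[kept]), 2, sdv[kept], "/")
  list(x = z, kept = kept)
}

#' Pixel-center coordinates for 0-based grid indices
#' @noRd
pixel_xy <- function(row, col, cell_size) {
  list(x = (col + 0.5) * cell_size, y = (row + 0.5) * cell_size)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
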