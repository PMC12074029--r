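# Internal helpers shared across modules.

#' Derive a child seed from a global seed and a stage tag
#'
#' All stochastic stages draw their own seed deterministically from one global
#' integer seed, so that a pipeline run is reproducible end to end while the
#' stages remain statistically independent.
#'
#' @param seed Integer global seed.
#' @param tag Character tag naming the consumer (e.g. `"emg"`, `"animal3"`).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # 32-bit multiplicative mix of the seed and the tag bytes; stays < 2^31.
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Coerce a data frame (first column may be time/ids) or matrix to a plain
# numeric matrix of time series, keeping column names.
as_ts_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("time series input must be a numeric matrix or data frame")
  }
  if (anyNA(x)) abort("time series contain missing values")
  x
}

#' Upper-triangle edge index table for an n-node network
#'
#' @param n Number of nodes.
#' @return A tibble with integer columns `i`, `j` (`i < j`), one row per
#'   unordered pair, in column-major upper-triangle order.
#' @export
edge_index <- function(n) {
  n <- assert_count(n, "n", min = 2L)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ord <- order(idx[, "col"], idx[, "row"])
  tibble(i = as.integer(idx[ord, "row"]), j = as.integer(idx[ord, "col"]))
}

# Extract upper-triangle values of a square matrix in edge_index() order.
ut_values <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix from upper-triangle values (diagonal given).
ut_matrix <- function(values, n, diag_value = NA_real_, dimnames = NULL) {
  m <- matrix(diag_value, n, n, dimnames = dimnames)
  m[upper.tri(m)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}
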