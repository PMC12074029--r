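#' Functional connectivity matrices
#'
#' An `fc_matrix` is a symmetric ROI-by-ROI matrix tagged with the domain its
#' entries live in: `"r"` (Pearson correlation; unit diagonal, off-diagonal in
#' \eqn{[-1, 1]}) or `"z"` (Fisher z = atanh(r); diagonal masked to `NA`
#' because z diverges at r = 1).
#'
#' @param values Symmetric numeric matrix.
#' @param domain `"r"` or `"z"`.
#' @param animal_id,group Optional provenance tags carried as attributes.
#' @return The matrix with class `fc_matrix` and attributes `domain`,
#'   `animal_id`, `group`.
#' @export
fc_matrix <- function(values, domain = c("r", "z"), animal_id = NULL, group = NULL) {
  domain <- match.arg(domain)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("`values` must be a square matrix")
  }
  off <- values[upper.tri(values)]
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8) {
    abort("`values` must be symmetric")
  }
  if (domain == "r") {
    if (any(abs(off) > 1 + 1e-12, na.rm = TRUE)) abort("r-domain values must lie in [-1, 1]")
    diag(values) <- 1
  } else {
    diag(values) <- NA_real_
  }
  structure(values, class = c("fc_matrix", "matrix", "array"),
            domain = domain, animal_id = animal_id, group = group)
}

fc_domain <- function(fc) attr(fc, "domain") %||% "r"

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix %dx%d, domain = %s%s>\n", nrow(x), ncol(x), fc_domain(x),
              if (!is.null(attr(x, "animal_id"))) paste0(", animal ", attr(x, "animal_id")) else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

#' Pearson correlation connectivity matrix from an ROI time-series matrix
#'
#' Builds the per-animal ROI-by-ROI functional connectivity matrix: the
#' Pearson correlation between every pair of ROI-averaged time series.  For
#' the shipped 31-ROI atlas with 300 volumes this is the standard
#' 31 x 31 per-animal matrix.
#'
#' @param ts Numeric matrix or data frame, rows = volumes (time points),
#'   columns = ROIs; column names are the ROI labels.  At least 3 rows, no
#'   missing values.
#' @param animal_id,group Optional provenance tags.
#' @return An [fc_matrix()] in the `r` domain (symmetric, unit diagonal).
#' @examples
#' ts <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(NULL, letters[1:5]))
#' fc <- pearson_fc(ts)
#' dim(fc)
#' @export
pearson_fc <- function(ts, animal_id = NULL, group = NULL) {
  x <- as_ts_matrix(ts)
  if (nrow(x) < 3L) abort("need at least 3 time points")
  v <- apply(x, 2L, var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0] %||% which(v == 0)
    abort(paste0("zero-variance ROI time series: ", paste(bad, collapse = ", ")))
  }
  r <- cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1   # guard numerical overshoot
  fc_matrix(r, "r", animal_id = animal_id, group = group)
}

#' Fisher z transform and its inverse
#'
#' `fisher_z()` maps an r-domain matrix elementwise to
#' \eqn{z = \tfrac12 \log\frac{1+r}{1-r} = \mathrm{atanh}(r)}, the
#' variance-stabilising transform under which group averaging and two-sample
#' tests on correlations are performed; `inverse_fisher_z()` maps back with
#' \eqn{r = \tanh(z)} for presentation.  Values with \eqn{|r| \ge 1 - \epsilon}
#' are clipped to \eqn{1 - \epsilon} (\eqn{\epsilon = 10^{-7}}) so z stays
#' finite; the diagonal is masked in the z domain.
#'
#' @param fc An [fc_matrix()] in the appropriate domain (plain matrices and
#'   scalars are accepted and transformed elementwise).
#' @return An [fc_matrix()] in the other domain (or a plain object matching
#'   the input shape).
#' @export
fisher_z <- function(fc) {
  eps <- 1e-7
  f <- function(r) atanh(pmin(pmax(r, -1 + eps), 1 - eps))
  if (inherits(fc, "fc_matrix")) {
    if (fc_domain(fc) != "r") abort("fisher_z() expects an r-domain matrix")
    fc_matrix(f(unclass(fc)), "z", animal_id = attr(fc, "animal_id"), group = attr(fc, "group"))
  } else {
    f(fc)
  }
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(fc) {
  if (inherits(fc, "fc_matrix")) {
    if (fc_domain(fc) != "z") abort("inverse_fisher_z() expects a z-domain matrix")
    r <- tanh(unclass(fc))
    diag(r) <- 1
    fc_matrix(r, "r", animal_id = attr(fc, "animal_id"), group = attr(fc, "group"))
  } else {
    tanh(fc)
  }
}

#' Group-average connectivity matrix
#'
#' Averages per-animal r-domain matrices into a group matrix.  By default the
#' average is taken in the Fisher-z domain (variance-stabilised) and converted
#' back to r; `average_domain = "r"` averages the correlations directly.
#'
#' @param matrices List of r-domain [fc_matrix()] objects with identical
#'   dimensions and ROI order.
#' @param average_domain `"z"` (default) or `"r"`.
#' @param group Optional group tag for the result.
#' @return An r-domain [fc_matrix()].
#' @export
group_mean_fc <- function(matrices, average_domain = c("z", "r"), group = NULL) {
  average_domain <- match.arg(average_domain)
  if (length(matrices) < 1L) abort("need at least one matrix")
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) != 1L ||
      length(unique(vapply(matrices, ncol, integer(1)))) != 1L) {
    abort("matrices must all have the same dimensions")
  }
  for (m in matrices) {
    if (inherits(m, "fc_matrix") && fc_domain(m) != "r") {
      abort("group_mean_fc() expects r-domain matrices")
    }
  }
  n <- dims[1]
  if (average_domain == "z") {
    zs <- lapply(matrices, function(m) unclass(fisher_z(fc_matrix(unclass(m), "r"))))
    zbar <- Reduce(`+`, zs) / length(zs)
    out <- tanh(zbar)
    diag(out) <- 1
  } else {
    out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
    diag(out) <- 1
  }
  dimnames(out) <- dimnames(matrices[[1]])
  fc_matrix(out, "r", group = group)
}
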