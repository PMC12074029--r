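#' Screening configuration for edge-wise group inference
#'
#' @param alpha Significance level applied to adjusted p-values (default 0.01,
#'   the level at which the significant edge set is defined).
#' @param correction `"bh_fdr"` (Benjamini-Hochberg false discovery rate,
#'   default) or `"bonferroni"` (family-wise error).
#' @param d_threshold Absolute Cohen's D cut for the large-effect set
#'   (default 0.8, the conventional "large effect" bound).
#' @param test_variant `"student"` (pooled-variance two-sample t, default) or
#'   `"welch"`.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.01, correction = c("bh_fdr", "bonferroni"),
                          d_threshold = 0.8, test_variant = c("student", "welch")) {
  assert_scalar_number(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  assert_scalar_number(d_threshold, "d_threshold", lo = 1e-12)
  structure(list(alpha = alpha, correction = match.arg(correction),
                 d_threshold = d_threshold, test_variant = match.arg(test_variant)),
            class = "screen_config")
}

# Stack the upper triangles of a list of z-domain fc matrices into an
# animals x edges matrix; validates shapes.
stack_edges <- function(matrices, arg = "matrices") {
  if (length(matrices) < 1L) abort(sprintf("`%s` is empty", arg))
  dims <- unique(vapply(matrices, nrow, integer(1)))
  if (length(dims) != 1L) abort(sprintf("`%s` have mixed dimensions", arg))
  for (m in matrices) {
    if (inherits(m, "fc_matrix") && fc_domain(m) != "z") {
      abort(sprintf("`%s` must be z-domain matrices (see fisher_z())", arg))
    }
  }
  do.call(rbind, lapply(matrices, ut_values))
}

# Vectorised two-sample t over the columns of animals x edges matrices.
# Returns list(t, p, df). Cross-checked against stats::t.test in the tests.
two_sample_t_cols <- function(a, b, variant = "student") {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, var); vb <- apply(b, 2L, var)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  zero <- which(!is.finite(t))
  if (length(zero)) {
    t[zero] <- 0
    p[zero] <- 1
  }
  list(t = t, p = p, df = df, zero_variance = zero)
}

#' Edge-wise two-sample tests between groups of connectivity matrices
#'
#' For every unordered ROI pair, performs a two-sample t-test on the animals'
#' Fisher-z connectivity values (group A minus group B), attaches adjusted
#' p-values and Cohen's D, and returns one record per edge.  This is the
#' inferential core of the network screen: with 31 ROIs it yields
#' 31*30/2 = 465 edge records.
#'
#' @param group_a,group_b Lists of z-domain [fc_matrix()] objects (one per
#'   animal), identical ROI order; at least 2 animals per group.
#' @param config A [screen_config()].
#' @return A tibble of class `edge_screen` with columns `i`, `j`, `roi_i`,
#'   `roi_j`, `t`, `p`, `p_adj`, `d`, `selected_significance`,
#'   `selected_effect`, `direction`.  Attributes record the config and group
#'   sizes.  Edges with zero pooled variance get `t = 0`, `p = 1` with a
#'   warning; edges whose pooled SD is zero have `d = NA` and are excluded
#'   from the effect set.
#' @examples
#' set.seed(1)
#' mk <- function() fisher_z(pearson_fc(matrix(rnorm(50 * 4), 50, 4)))
#' res <- edgewise_ttest(replicate(4, mk(), simplify = FALSE),
#'                       replicate(4, mk(), simplify = FALSE))
#' head(res)
#' @export
edgewise_ttest <- function(group_a, group_b, config = screen_config()) {
  za <- stack_edges(group_a, "group_a")
  zb <- stack_edges(group_b, "group_b")
  if (nrow(za) < 2L || nrow(zb) < 2L) abort("need at least 2 animals per group")
  if (ncol(za) != ncol(zb)) abort("groups have mixed ROI sets")
  n <- nrow(group_a[[1]])
  tt <- two_sample_t_cols(za, zb, config$test_variant)
  if (length(tt$zero_variance)) {
    warn(sprintf("%d edge(s) with zero pooled variance: t set to 0, p to 1",
                 length(tt$zero_variance)))
  }
  d <- cohens_d_cols(za, zb, warn_masked = FALSE)
  p_adj <- adjust_pvalues(tt$p, config$correction)
  idx <- edge_index(n)
  rois <- rownames(group_a[[1]]) %||% paste0("ROI", seq_len(n))
  out <- tibble(
    i = idx$i, j = idx$j,
    roi_i = rois[idx$i], roi_j = rois[idx$j],
    t = tt$t, p = tt$p, p_adj = p_adj, d = d,
    selected_significance = p_adj < config$alpha,
    selected_effect = !is.na(d) & abs(d) > config$d_threshold,
    direction = dplyr::if_else(dplyr::coalesce(d, tt$t) > 0, "enhanced", "reduced")
  )
  structure(out, class = c("edge_screen", class(out)),
            config = config, n_a = nrow(za), n_b = nrow(zb), n_rois = n)
}

#' Multiple-testing adjustment of p-values
#'
#' Benjamini-Hochberg step-up FDR adjustment (`"bh_fdr"`) or Bonferroni
#' family-wise correction (`"bonferroni"`), both capped at 1.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method `"bh_fdr"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh_fdr", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = switch(method, bh_fdr = "BH", bonferroni = "bonferroni"))
}

cohens_d_cols <- function(a, b, warn_masked = TRUE) {
  na <- nrow(a); nb <- nrow(b)
  sp <- sqrt(((na - 1) * apply(a, 2L, var) + (nb - 1) * apply(b, 2L, var)) /
               (na + nb - 2))
  d <- (colMeans(a) - colMeans(b)) / sp
  masked <- !is.finite(d)
  if (any(masked)) {
    d[masked] <- NA_real_
    if (warn_masked) {
      warn(sprintf("Cohen's D undefined (zero pooled SD) at %d edge(s); masked",
                   sum(masked)))
    }
  }
  d
}

#' Cohen's D effect-size matrix between two groups
#'
#' Standardised mean difference of Fisher-z connectivity at every edge:
#' \eqn{D = (\bar z_A - \bar z_B) / s_{pooled}} over animals, so positive D
#' means stronger connectivity in group A (the treated group by convention).
#' Effect sizes above 0.8 in magnitude are conventionally "large".
#'
#' @inheritParams edgewise_ttest
#' @return A symmetric numeric matrix of D values with `NA` diagonal; edges
#'   with zero pooled SD are masked to `NA` with a warning.
#' @export
cohens_d_matrix <- function(group_a, group_b) {
  za <- stack_edges(group_a, "group_a")
  zb <- stack_edges(group_b, "group_b")
  if (nrow(za) < 2L || nrow(zb) < 2L) abort("need at least 2 animals per group")
  n <- nrow(group_a[[1]])
  d <- cohens_d_cols(za, zb)
  ut_matrix(d, n, diag_value = NA_real_,
            dimnames = dimnames(group_a[[1]]))
}

#' Multi-parameter edge screen
#'
#' Splits the tested edges into the significance set (adjusted p below alpha),
#' the large-effect set (|D| above the threshold), their intersection (the
#' multi-parameter screen), and enhanced/reduced directions within each.
#'
#' @param results An `edge_screen` tibble from [edgewise_ttest()].
#' @param config A [screen_config()]; defaults to the config stored in
#'   `results`.
#' @return A list of class `screen_sets` with tibbles `significance`,
#'   `effect`, `intersection` (each a subset of `results`), plus `config`.
#' @export
screen_edges <- function(results, config = NULL) {
  config <- config %||% attr(results, "config") %||% screen_config()
  sig <- results[!is.na(results$p_adj) & results$p_adj < config$alpha, ]
  eff <- results[!is.na(results$d) & abs(results$d) > config$d_threshold, ]
  both <- dplyr::semi_join(sig, eff, by = c("i", "j"))
  structure(list(significance = sig, effect = eff, intersection = both,
                 config = config),
            class = "screen_sets")
}

#' @export
print.screen_sets <- function(x, ...) {
  cat(sprintf(
    "<screen_sets: %d significant (alpha = %g, %s), %d large-effect (|D| > %g), %d in both>\n",
    nrow(x$significance), x$config$alpha, x$config$correction,
    nrow(x$effect), x$config$d_threshold, nrow(x$intersection)))
  invisible(x)
}

#' @method tidy screen_sets
#' @export
tidy.screen_sets <- function(x, ...) {
  dplyr::bind_rows(
    significance = x$significance, effect = x$effect,
    intersection = x$intersection, .id = "set"
  )
}

#' @method glance screen_sets
#' @export
glance.screen_sets <- function(x, ...) {
  tibble(
    n_significant = nrow(x$significance),
    n_effect = nrow(x$effect),
    n_intersection = nrow(x$intersection),
    n_enhanced = sum(x$significance$direction == "enhanced"),
    n_reduced = sum(x$significance$direction == "reduced"),
    alpha = x$config$alpha, correction = x$config$correction,
    d_threshold = x$config$d_threshold
  )
}
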