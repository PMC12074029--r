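#' Node Modulation Index (NMI)
#'
#' Per-ROI summary of connectivity change: for each ROI, its n-1 connections
#' are ranked by absolute effect size |D| and the NMI is the mean signed
#' Cohen's D over the top `fraction` of them (k = ceiling(fraction * (n-1)),
#' so k >= 1 always; with 31 ROIs and the default 10% fraction each ROI
#' averages its 3 strongest connections).  Ties in |D| are broken by the
#' smaller partner index so the selection is deterministic.
#'
#' @param D Symmetric effect-size matrix (e.g. from [cohens_d_matrix()]),
#'   diagonal masked/ignored.  `NA` entries are excluded from ranking; a fully
#'   masked row is an error.
#' @param fraction Fraction of each ROI's connections to average, in (0, 1\];
#'   default 0.10.  `fraction = 1` reduces the NMI to the plain row mean.
#' @param absolute If `TRUE`, average |D| instead of signed D.
#' @return A tibble of class `nmi_result` with columns `roi`, `nmi`, `rank`,
#'   and a list-column `contributing` of partner-ROI index vectors; rows are
#'   in original ROI order, `rank` gives the position by descending |NMI|
#'   (ties broken by ROI name).
#' @examples
#' D <- matrix(0, 4, 4); D[1, 3] <- D[3, 1] <- 0.9
#' node_modulation_index(D)
#' @export
node_modulation_index <- function(D, fraction = 0.10, absolute = FALSE) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square matrix")
  D <- unclass(D)
  n <- nrow(D)
  assert_scalar_number(fraction, "fraction", lo = 1e-12, hi = 1)
  rois <- rownames(D) %||% paste0("ROI", seq_len(n))
  k <- as.integer(ceiling(fraction * (n - 1L)))
  nmi <- numeric(n)
  contributing <- vector("list", n)
  for (i in seq_len(n)) {
    partners <- setdiff(seq_len(n), i)
    vals <- D[i, partners]
    ok <- !is.na(vals)
    if (!any(ok)) abort(sprintf("all effect sizes masked for ROI %s", rois[i]))
    partners <- partners[ok]; vals <- vals[ok]
    ki <- min(k, length(vals))
    # rank by |D| descending; ties broken by smaller partner index
    ord <- order(-abs(vals), partners)
    top <- ord[seq_len(ki)]
    contributing[[i]] <- partners[top]
    nmi[i] <- mean(if (absolute) abs(vals[top]) else vals[top])
  }
  out <- tibble(roi = rois, nmi = nmi, contributing = contributing)
  out$rank <- rank_by_magnitude(out$nmi, out$roi)
  out <- out[, c("roi", "nmi", "rank", "contributing")]
  structure(out, class = c("nmi_result", class(out)),
            fraction = fraction, k = k, absolute = absolute)
}

# Rank positions by descending |value|, stable alphabetical tie-break.
rank_by_magnitude <- function(values, names) {
  ord <- order(-abs(values), names)
  rnk <- integer(length(values))
  rnk[ord] <- seq_along(values)
  rnk
}

#' Rank ROIs by absolute Node Modulation Index
#'
#' @param nmi An `nmi_result` from [node_modulation_index()].
#' @return The same tibble reordered by descending |NMI| (ties broken
#'   alphabetically by ROI name).
#' @export
rank_rois <- function(nmi) {
  if (!inherits(nmi, "nmi_result")) abort("`nmi` must be an nmi_result")
  nmi[order(nmi$rank), ]
}

#' @method tidy nmi_result
#' @export
tidy.nmi_result <- function(x, ...) {
  tibble(roi = x$roi, nmi = x$nmi, rank = x$rank,
         n_contributing = lengths(x$contributing))
}

#' @method glance nmi_result
#' @export
glance.nmi_result <- function(x, ...) {
  tibble(n_rois = nrow(x), k = attr(x, "k"), fraction = attr(x, "fraction"),
         absolute = attr(x, "absolute"), max_abs_nmi = max(abs(x$nmi)))
}
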