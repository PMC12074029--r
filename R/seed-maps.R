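#' Mean time course over a seed mask
#'
#' Unweighted mean of the voxel time series inside the seed mask, matching
#' the ROI-averaged time-series convention used for the matrix pipeline.
#'
#' @param vol A `voxel_series` (see [simulate_voxel_volume()]) or a plain 4-D
#'   array (x, y, z, t).
#' @param seed_mask Logical 3-D array; must be nonempty and lie inside the
#'   brain mask.
#' @return Numeric vector of length t.
#' @export
seed_timecourse <- function(vol, seed_mask) {
  d4 <- voxel_data(vol)
  if (!all(dim(seed_mask) == dim(d4)[1:3])) abort("seed mask must match grid")
  idx <- which(seed_mask)
  if (length(idx) == 0L) abort("seed mask is empty")
  bm <- if (is.list(vol)) vol$brain_mask else NULL
  if (!is.null(bm) && any(!bm[seed_mask])) abort("seed mask extends outside the brain mask")
  flat <- matrix(d4, prod(dim(d4)[1:3]), dim(d4)[4])
  colMeans(flat[idx, , drop = FALSE])
}

voxel_data <- function(vol) {
  d4 <- if (is.list(vol)) vol$data else vol
  if (!is.array(d4) || length(dim(d4)) != 4L) abort("need a 4-D (x, y, z, t) array")
  if (dim(d4)[4] < 3L) abort("need at least 3 time points")
  d4
}

#' Voxel-wise seed correlation map
#'
#' Pearson correlation of every in-mask voxel's time series with the seed
#' time course; optionally Fisher-z transformed for group statistics.
#' Zero-variance voxels are masked to `NA`.
#'
#' @param vol A `voxel_series` or 4-D array.
#' @param seed_series Numeric seed time course, length t (e.g. from
#'   [seed_timecourse()]).
#' @param domain `"r"` (default) or `"z"`.
#' @return A list of class `seed_map`: `map` (3-D array), `domain`.
#' @export
seed_correlation_map <- function(vol, seed_series, domain = c("r", "z")) {
  domain <- match.arg(domain)
  d4 <- voxel_data(vol)
  nt <- dim(d4)[4]
  if (length(seed_series) != nt) abort("seed series length must equal the number of volumes")
  if (sd(seed_series) == 0) abort("seed series is constant")
  flat <- matrix(d4, prod(dim(d4)[1:3]), nt)
  sc <- as.numeric(scale(seed_series))
  vm <- rowMeans(flat)
  xc <- flat - vm
  ssd <- sqrt(rowSums(xc^2))
  r <- as.numeric(xc %*% sc) / (ssd * sqrt(nt - 1))
  r[ssd == 0] <- NA_real_
  r[r > 1] <- 1; r[r < -1] <- -1
  bm <- if (is.list(vol)) vol$brain_mask else NULL
  if (!is.null(bm)) r[!as.logical(bm)] <- NA_real_
  m <- array(if (domain == "z") fisher_z(r) else r, dim(d4)[1:3])
  structure(list(map = m, domain = domain), class = "seed_map")
}

#' Group t-map from per-animal seed maps
#'
#' Voxel-wise two-sample t-test (group A minus group B) on Fisher-z seed
#' maps, with an optional BH-FDR significance mask.
#'
#' @param maps_a,maps_b Lists of z-domain `seed_map` objects on identical
#'   grids, at least 2 per group.
#' @param fdr_alpha If non-`NULL`, also return a logical mask of voxels with
#'   BH-adjusted p below this level.
#' @param variant `"student"` or `"welch"`.
#' @return A list of class `seed_tmap`: `t` (3-D t map), `p` (3-D p map),
#'   `significant` (logical 3-D mask or `NULL`), `n_a`, `n_b`.
#' @export
group_seed_tmap <- function(maps_a, maps_b, fdr_alpha = NULL, variant = "student") {
  get <- function(m) {
    if (!inherits(m, "seed_map") || m$domain != "z") abort("maps must be z-domain seed_map objects")
    m$map
  }
  za <- lapply(maps_a, get); zb <- lapply(maps_b, get)
  if (length(za) < 2L || length(zb) < 2L) abort("need at least 2 maps per group")
  dims <- unique(c(lapply(za, dim), lapply(zb, dim)))
  if (length(dims) != 1L) abort("seed maps are on mismatched grids")
  d <- dims[[1]]
  A <- do.call(rbind, lapply(za, as.numeric))
  B <- do.call(rbind, lapply(zb, as.numeric))
  ok <- complete.cases(t(A)) & complete.cases(t(B))
  tt <- two_sample_t_cols(A[, ok, drop = FALSE], B[, ok, drop = FALSE], variant)
  tmap <- pmap <- rep(NA_real_, prod(d))
  tmap[ok] <- tt$t; pmap[ok] <- tt$p
  sig <- NULL
  if (!is.null(fdr_alpha)) {
    padj <- rep(NA_real_, prod(d))
    padj[ok] <- adjust_pvalues(tt$p, "bh_fdr")
    sig <- array(!is.na(padj) & padj < fdr_alpha, d)
  }
  structure(list(t = array(tmap, d), p = array(pmap, d), significant = sig,
                 n_a = length(za), n_b = length(zb)),
            class = "seed_tmap")
}

#' Dice overlap of two masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return 2|A∩B| / (|A| + |B|).
#' @export
dice_overlap <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Read/write NIfTI volumes
#'
#' Thin wrappers over RNifti for exchanging 3-D maps / 4-D series and masks
#' with standard neuroimaging tools.
#'
#' @param path NIfTI file path.
#' @param x Numeric/logical array to write.
#' @param voxel_size_mm Voxel dimensions in mm (length 3).
#' @return `read_nifti()` returns an array; `write_nifti()` the path,
#'   invisibly.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "pixdim") <- RNifti::pixdim(img)
  a
}

#' @rdname read_nifti
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(0.2, 0.2, 0.5)) {
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, length(dim(x)) - 3))[seq_along(dim(x))]
  RNifti::writeNifti(img, path)
  invisible(path)
}
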