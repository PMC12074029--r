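#' Cuboid mask helper
#'
#' @param dim 3-element spatial grid size.
#' @param center 3-element center voxel (1-based).
#' @param radius Half-width in voxels (0 gives a single voxel).
#' @return A logical 3-D array.
#' @export
cube_mask <- function(dim, center, radius = 1) {
  m <- array(FALSE, dim)
  rng <- function(c, r, n) max(1, c - r):min(n, c + r)
  m[rng(center[1], radius, dim[1]),
    rng(center[2], radius, dim[2]),
    rng(center[3], radius, dim[3])] <- TRUE
  m
}

#' Simulate a 4-D voxel volume with a planted seed-correlated region
#'
#' Voxels inside `region_mask` share a latent signal with the seed at
#' `target_corr`; voxels outside are independent Gaussian noise.  Seed voxels
#' carry the latent signal with a small additive noise (`seed_noise_sd`), so
#' the seed-mask mean time course tracks the latent signal nearly perfectly
#' and each planted voxel correlates with it at approximately `target_corr`.
#'
#' @param dim 3-element spatial grid (e.g. `c(20, 20, 20)`).
#' @param n_volumes Number of time points (>= 3).
#' @param seed_mask Logical 3-D array marking seed voxels (nonempty).
#' @param region_mask Logical 3-D array marking the planted region; `NULL`
#'   for none.
#' @param target_corr Correlation of planted-region voxels with the latent
#'   seed signal, |target_corr| < 1.
#' @param seed Integer RNG seed.
#' @param seed_noise_sd SD of noise added to seed voxels (default 0.1).
#' @param noise_share Fraction (0-1) of the planted-region noise variance
#'   shared across its voxels (default 0, independent voxel noise).  Values
#'   near 1 emulate spatially smoothed data in which neighbouring voxels
#'   carry common noise, making region-averaged and voxel-averaged
#'   correlations agree.
#' @param allow_overlap Allow seed and planted masks to overlap (default
#'   `FALSE`; overlap without this flag is an error).
#' @return A list of class `voxel_series`: `data` (4-D array x,y,z,t),
#'   `brain_mask`, `seed_mask`, `region_mask`, `latent` (length-t latent
#'   signal), `target_corr`, `voxel_size_mm`.
#' @export
simulate_voxel_volume <- function(dim, n_volumes, seed_mask, region_mask = NULL,
                                  target_corr = 0.8, seed = 1,
                                  seed_noise_sd = 0.1, noise_share = 0,
                                  allow_overlap = FALSE) {
  assert_scalar_number(noise_share, "noise_share", lo = 0, hi = 1)
  stopifnot(length(dim) == 3L)
  n_volumes <- assert_count(n_volumes, "n_volumes", min = 3L)
  assert_scalar_number(target_corr, "target_corr", lo = -1 + 1e-9, hi = 1 - 1e-9)
  if (!is.array(seed_mask) || !all(dim(seed_mask) == dim)) abort("seed mask must match grid")
  if (!any(seed_mask)) abort("seed mask is empty")
  if (!is.null(region_mask)) {
    if (!all(dim(region_mask) == dim)) abort("region mask must match grid")
    if (!allow_overlap && any(seed_mask & region_mask)) {
      abort("seed and planted region masks overlap; pass allow_overlap = TRUE if intended")
    }
  }
  set.seed(derive_seed(seed, "voxel"))
  nvox <- prod(dim)
  latent <- rnorm(n_volumes)
  flat <- matrix(rnorm(nvox * n_volumes), nvox, n_volumes)
  sidx <- which(seed_mask)
  flat[sidx, ] <- (rep(1, length(sidx)) %o% latent + seed_noise_sd * flat[sidx, , drop = FALSE]) /
    sqrt(1 + seed_noise_sd^2)
  if (!is.null(region_mask)) {
    ridx <- which(region_mask & !seed_mask)
    noise <- flat[ridx, , drop = FALSE]
    if (noise_share > 0) {
      shared <- rnorm(n_volumes)
      noise <- sqrt(noise_share) * (rep(1, length(ridx)) %o% shared) +
        sqrt(1 - noise_share) * noise
    }
    flat[ridx, ] <- target_corr * (rep(1, length(ridx)) %o% latent) +
      sqrt(1 - target_corr^2) * noise
  }
  structure(
    list(data = array(flat, c(dim, n_volumes)),
         brain_mask = array(TRUE, dim),
         seed_mask = seed_mask, region_mask = region_mask,
         latent = latent, target_corr = target_corr, voxel_size_mm = c(0.2, 0.2, 0.5)),
    class = "voxel_series")
}

#' Specification of a synthetic EMG recording
#'
#' The generated signal is a sum of band-limited Gaussian noise components
#' (one per row of `bands`, each normalised to unit variance then scaled by
#' its gain, so the expected power in a band is the squared gain) plus a
#' mains sinusoid.  A wake/sleep label track alternates in fixed-period
#' blocks with the requested wake fraction; sleep samples are attenuated.
#'
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration_s Recording length in seconds.
#' @param bands Data frame with columns `lo`, `hi` (Hz) and `gain` (linear);
#'   default bands 2-20 (gain 0.5), 20-50 (1) and 50-150 Hz (1), the motor
#'   ranges analysed downstream.
#' @param mains_hz Mains frequency (default 50 Hz).
#' @param mains_amp Mains sinusoid amplitude (default 0.2).
#' @param wake_fraction Fraction of each block cycle spent awake, in (0, 1].
#' @param block_s Label block cycle length in seconds (default 30).
#' @param sleep_attenuation Multiplier applied to sleep samples (default 0.3).
#' @param seed Integer seed.
#' @return A list of class `emg_spec`.
#' @export
emg_spec <- function(fs = 1000, duration_s = 60,
                     bands = data.frame(lo = c(2, 20, 50), hi = c(20, 50, 150),
                                        gain = c(0.5, 1, 1)),
                     mains_hz = 50, mains_amp = 0.2, wake_fraction = 0.8,
                     block_s = 30, sleep_attenuation = 0.3, seed = 1) {
  assert_scalar_number(fs, "fs", lo = 1e-9)
  assert_scalar_number(duration_s, "duration_s", lo = 1e-9)
  bands <- as_tibble(bands)
  stopifnot(all(c("lo", "hi", "gain") %in% names(bands)))
  if (any(bands$lo < 0) || any(bands$hi <= bands$lo) || any(bands$hi > fs / 2)) {
    abort("band edges must satisfy 0 <= lo < hi <= fs/2")
  }
  assert_scalar_number(wake_fraction, "wake_fraction", lo = 1e-9, hi = 1)
  lo_min <- min(bands$lo[bands$lo > 0], Inf)
  if (is.finite(lo_min) && duration_s < 2 / lo_min) {
    abort(sprintf("duration too short: need >= 2 cycles of the lowest band (%g s)", 2 / lo_min))
  }
  structure(list(fs = fs, duration_s = duration_s, bands = bands,
                 mains_hz = mains_hz, mains_amp = mains_amp,
                 wake_fraction = wake_fraction, block_s = block_s,
                 sleep_attenuation = sleep_attenuation, seed = as.integer(seed)),
            class = "emg_spec")
}

# Band-limited unit-variance Gaussian noise via FFT masking.
bandlimited_noise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  keep <- freqs >= lo & freqs < hi
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) abort("degenerate band: no frequency bins inside it")
  y / s
}

#' Simulate a labeled EMG recording
#'
#' @param spec An [emg_spec()].
#' @param animal_id,group Optional provenance tags.
#' @return A list of class `signal_recording`: `samples` (mV), `fs`, `state`
#'   (character vector `"wake"`/`"sleep"`, one per sample), `animal_id`,
#'   `group`.
#' @examples
#' rec <- simulate_emg(emg_spec(duration_s = 10, seed = 7))
#' length(rec$samples) / rec$fs
#' @export
simulate_emg <- function(spec, animal_id = NULL, group = NULL) {
  stopifnot(inherits(spec, "emg_spec"))
  set.seed(derive_seed(spec$seed, paste0("emg_", animal_id %||% "x")))
  n <- round(spec$fs * spec$duration_s)
  x <- numeric(n)
  for (k in seq_len(nrow(spec$bands))) {
    g <- spec$bands$gain[k]
    if (g != 0) {
      x <- x + g * bandlimited_noise(n, spec$fs, spec$bands$lo[k], spec$bands$hi[k])
    }
  }
  if (spec$mains_amp != 0) {
    phi <- runif(1, 0, 2 * pi)
    x <- x + spec$mains_amp * sin(2 * pi * spec$mains_hz * (seq_len(n) - 1) / spec$fs + phi)
  }
  # deterministic block-cycled wake/sleep label track
  block <- round(spec$block_s * spec$fs)
  wake_len <- round(spec$wake_fraction * block)
  in_cycle <- ((seq_len(n) - 1) %% block) < wake_len
  state <- ifelse(in_cycle, "wake", "sleep")
  x[state == "sleep"] <- x[state == "sleep"] * spec$sleep_attenuation
  signal_recording(x, spec$fs, state, animal_id = animal_id, group = group)
}

#' Construct a signal recording
#'
#' @param samples Numeric signal (mV).
#' @param fs Sampling rate (Hz).
#' @param state Per-sample state labels (`"wake"`/`"sleep"`); default all wake.
#' @param animal_id,group Optional tags.
#' @return A list of class `signal_recording`.
#' @export
signal_recording <- function(samples, fs, state = NULL, animal_id = NULL, group = NULL) {
  assert_scalar_number(fs, "fs", lo = 1e-9)
  samples <- as.numeric(samples)
  state <- state %||% rep("wake", length(samples))
  if (length(state) != length(samples)) abort("state labels must match sample count")
  structure(list(samples = samples, fs = fs, state = as.character(state),
                 animal_id = animal_id, group = group),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording: %.1f s at %g Hz, %.0f%% wake%s>\n",
              length(x$samples) / x$fs, x$fs, 100 * mean(x$state == "wake"),
              if (!is.null(x$animal_id)) paste0(", animal ", x$animal_id) else ""))
  invisible(x)
}

#' Specification of a synthetic axon population
#'
#' Inner (axonal) diameters follow a log-normal law; each axon's g-ratio is a
#' baseline plus an optional diameter trend, plus (for the treated group
#' only) a shift applied below the diameter threshold, plus Gaussian noise,
#' clipped into (0, 1).  Outer diameter is `inner / g`, so inner < outer by
#' construction.
#'
#' @param n_axons Axons per group (default 500).
#' @param diameter_meanlog,diameter_sdlog Log-normal parameters of the inner
#'   diameter in nm (defaults `log(400)` and 0.4).
#' @param gratio_baseline Baseline g-ratio (default 0.75).
#' @param gratio_shift Additive g shift applied in the treated group below
#'   the threshold (default -0.05; negative = thicker myelin).
#' @param threshold_nm Diameter threshold in nm (default 400).
#' @param noise_sd SD of per-axon g noise (default 0.05).
#' @param gratio_slope_per_nm Linear g-vs-diameter trend around the
#'   threshold (default 0).
#' @param seed Integer seed.
#' @return A list of class `axon_spec`.
#' @export
axon_spec <- function(n_axons = 500, diameter_meanlog = log(400),
                      diameter_sdlog = 0.4, gratio_baseline = 0.75,
                      gratio_shift = -0.05, threshold_nm = 400,
                      noise_sd = 0.05, gratio_slope_per_nm = 0, seed = 1) {
  n_axons <- assert_count(n_axons, "n_axons")
  assert_scalar_number(threshold_nm, "threshold_nm", lo = 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", lo = 0)
  for (g in c(gratio_baseline, gratio_baseline + gratio_shift)) {
    if (g - 3 * noise_sd <= 0 || g + 3 * noise_sd >= 1) {
      abort("g-ratio law places the bulk of axons outside (0, 1)")
    }
  }
  structure(list(n_axons = n_axons, diameter_meanlog = diameter_meanlog,
                 diameter_sdlog = diameter_sdlog, gratio_baseline = gratio_baseline,
                 gratio_shift = gratio_shift, threshold_nm = threshold_nm,
                 noise_sd = noise_sd, gratio_slope_per_nm = gratio_slope_per_nm,
                 seed = as.integer(seed)),
            class = "axon_spec")
}

#' Simulate an axon measurement table
#'
#' @param spec An [axon_spec()].
#' @param group `"treated"` (g shift applied below threshold) or `"control"`.
#' @param region Optional region label (e.g. `"CC"`, `"MO"`).
#' @return A tibble with columns `group`, `region`, `inner_nm`, `outer_nm`;
#'   every row satisfies `inner_nm < outer_nm`.
#' @export
simulate_axons <- function(spec, group = c("control", "treated"), region = NA_character_) {
  stopifnot(inherits(spec, "axon_spec"))
  group <- match.arg(group)
  set.seed(derive_seed(spec$seed, paste0("axons_", group, "_", region)))
  inner <- stats::rlnorm(spec$n_axons, spec$diameter_meanlog, spec$diameter_sdlog)
  g <- spec$gratio_baseline +
    spec$gratio_slope_per_nm * (inner - spec$threshold_nm) +
    ifelse(group == "treated" & inner < spec$threshold_nm, spec$gratio_shift, 0) +
    rnorm(spec$n_axons, 0, spec$noise_sd)
  g <- pmin(pmax(g, 0.02), 0.98)
  tibble(group = group, region = region, inner_nm = inner, outer_nm = inner / g)
}

#' Simulate a binary fiber image with known length and crossings
#'
#' Draws smooth random curves (unit steps with slowly drifting heading,
#' reflected at the borders), rasterises them one pixel wide, and returns the
#' analytic polyline length under the chain-code convention (1 per
#' axis-aligned inter-pixel step, sqrt(2) per diagonal step) plus the number
#' of crossing clusters where distinct curves overlap.
#'
#' @param n_curves Number of curves.
#' @param curve_length_px Steps per curve.
#' @param image_size 2-element pixel size (rows, cols).
#' @param heading_sd SD of the per-step heading increment in radians
#'   (default 0.15; smaller = straighter fibers).
#' @param seed Integer seed.
#' @return A list of class `fiber_sim`: `image` (logical matrix), `length_px`
#'   (total ground-truth chain length), `n_crossings`, `curves` (list of
#'   2-column pixel coordinate matrices).
#' @export
simulate_fiber_image <- function(n_curves, curve_length_px, image_size = c(256, 256),
                                 heading_sd = 0.15, seed = 1) {
  n_curves <- assert_count(n_curves, "n_curves")
  curve_length_px <- assert_count(curve_length_px, "curve_length_px", min = 2L)
  if (min(image_size) < 16 || n_curves * curve_length_px > 4 * prod(image_size)) {
    abort("image too small for the requested curves")
  }
  set.seed(derive_seed(seed, "fibers"))
  img <- matrix(FALSE, image_size[1], image_size[2])
  owner <- matrix(0L, image_size[1], image_size[2])  # first curve to paint each pixel
  multi <- matrix(FALSE, image_size[1], image_size[2])
  total_len <- 0
  curves <- vector("list", n_curves)
  for (cidx in seq_len(n_curves)) {
    pos <- c(runif(1, 4, image_size[1] - 3), runif(1, 4, image_size[2] - 3))
    theta <- runif(1, 0, 2 * pi)
    px <- matrix(NA_real_, curve_length_px + 1L, 2L)
    px[1, ] <- round(pos)
    for (s in seq_len(curve_length_px)) {
      theta <- theta + rnorm(1, 0, heading_sd)
      step <- c(cos(theta), sin(theta))
      nxt <- pos + step
      # reflect at borders
      if (nxt[1] < 2 || nxt[1] > image_size[1] - 1) { theta <- pi - theta; nxt <- pos + c(cos(theta), sin(theta)) }
      if (nxt[2] < 2 || nxt[2] > image_size[2] - 1) { theta <- -theta; nxt <- pos + c(cos(theta), sin(theta)) }
      pos <- pmin(pmax(nxt, 2), image_size - 1)
      px[s + 1L, ] <- round(pos)
    }
    # drop consecutive duplicate pixels
    keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
    px <- px[keep, , drop = FALSE]
    steps <- abs(diff(px))
    total_len <- total_len + sum(ifelse(rowSums(steps) == 2, sqrt(2), 1))
    for (k in seq_len(nrow(px))) {
      r <- px[k, 1]; c2 <- px[k, 2]
      if (img[r, c2] && owner[r, c2] != cidx) multi[r, c2] <- TRUE
      img[r, c2] <- TRUE
      if (owner[r, c2] == 0L) owner[r, c2] <- cidx
    }
    curves[[cidx]] <- px
  }
  n_crossings <- if (any(multi)) length(cluster_pixels(which(multi, arr.ind = TRUE), dim(multi))) else 0L
  structure(list(image = img, length_px = total_len, n_crossings = n_crossings,
                 curves = curves),
            class = "fiber_sim")
}
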