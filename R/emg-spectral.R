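#' Extract wake-labeled samples from a recording
#'
#' Keeps only wake-labeled samples, concatenated, while recording the
#' original run boundaries so that windowed statistics never straddle a gap
#' between two wake periods.
#'
#' @param rec A [signal_recording()].
#' @return A [signal_recording()] of wake samples only, with attribute
#'   `segments`: a tibble (`start`, `end`, indices into the concatenated
#'   output) with one row per original wake run.
#' @export
extract_wake <- function(rec) {
  stopifnot(inherits(rec, "signal_recording"))
  wake <- rec$state == "wake"
  if (!any(wake)) abort("recording contains no wake samples")
  runs <- rle(wake)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  lens <- runs$lengths[keep]
  seg_end <- cumsum(lens)
  segments <- tibble(start = seg_end - lens + 1L, end = seg_end)
  out <- signal_recording(rec$samples[wake], rec$fs,
                          state = rep("wake", sum(wake)),
                          animal_id = rec$animal_id, group = rec$group)
  attr(out, "segments") <- segments
  out
}

rec_segments <- function(rec) {
  attr(rec, "segments") %||% tibble(start = 1L, end = length(rec$samples))
}

#' RMS amplitude envelope
#'
#' Quadratic-mean amplitude over consecutive non-overlapping windows
#' (default 1 s).  Windows are laid out within each wake segment
#' independently, so none straddles a gap; trailing samples shorter than a
#' window are dropped.
#'
#' @param rec A [signal_recording()] (typically wake-only, see
#'   [extract_wake()]).
#' @param window_s Window length in seconds (must contain at least 2
#'   samples).
#' @return Numeric vector of per-window RMS values (signal units).
#' @export
rms_envelope <- function(rec, window_s = 1.0) {
  stopifnot(inherits(rec, "signal_recording"))
  w <- round(window_s * rec$fs)
  if (w < 2) abort("window must contain at least 2 samples")
  segs <- rec_segments(rec)
  env <- numeric(0)
  for (k in seq_len(nrow(segs))) {
    x <- rec$samples[segs$start[k]:segs$end[k]]
    nw <- length(x) %/% w
    if (nw >= 1) {
      m <- matrix(x[seq_len(nw * w)], w, nw)
      env <- c(env, sqrt(colMeans(m^2)))
    }
  }
  if (length(env) == 0L) abort("window longer than every wake segment")
  env
}

#' Amplitude summary of an envelope
#'
#' @param envelope Numeric envelope values (e.g. from [rms_envelope()]).
#' @return A tibble with columns `max` and `mean`.
#' @export
amplitude_stats <- function(envelope) {
  if (length(envelope) == 0L) abort("empty envelope")
  tibble(max = max(envelope), mean = mean(envelope))
}

#' Welch power spectral density
#'
#' Mean-removed, Hann-windowed, overlapping-segment averaged periodogram.
#' One-sided density in signal-units^2/Hz on a grid of spacing
#' `1 / segment_s`; satisfies Parseval (integrated density approximates the
#' signal variance).  Segments are laid out within wake segments so none
#' straddles a gap.
#'
#' @param rec A [signal_recording()] or numeric vector (then `fs` must be
#'   given).
#' @param segment_s Welch segment length in seconds (default 4, i.e. 0.25 Hz
#'   resolution at 1 kHz).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param fs Sampling rate, required when `rec` is a bare vector.
#' @return A tibble of class `spectral_result` with columns `frequency` (Hz)
#'   and `density`; attributes `fs`, `n_segments`, `variance` (of the
#'   analysed signal).
#' @export
welch_psd <- function(rec, segment_s = 4.0, overlap = 0.5, fs = NULL) {
  if (is.numeric(rec)) rec <- signal_recording(rec, fs %||% abort("`fs` required"))
  stopifnot(inherits(rec, "signal_recording"))
  nseg <- round(segment_s * rec$fs)
  if (nseg < 8) abort("Welch segment too short")
  step <- max(1L, round(nseg * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  W <- sum(win^2)
  acc <- numeric(nseg)
  count <- 0L
  allx <- numeric(0)
  segs <- rec_segments(rec)
  for (k in seq_len(nrow(segs))) {
    x <- rec$samples[segs$start[k]:segs$end[k]]
    allx <- c(allx, x)
    if (length(x) < nseg) next
    starts <- seq(1L, length(x) - nseg + 1L, by = step)
    for (s in starts) {
      seg <- x[s:(s + nseg - 1L)]
      seg <- (seg - mean(seg)) * win
      acc <- acc + Mod(fft(seg))^2
      count <- count + 1L
    }
  }
  if (count == 0L) abort("recording shorter than one Welch segment")
  pxx2 <- acc / count / (rec$fs * W)         # two-sided density
  nhalf <- nseg %/% 2
  freq <- (0:nhalf) * rec$fs / nseg
  dens <- pxx2[1:(nhalf + 1)]
  scale2 <- rep(2, nhalf + 1)
  scale2[1] <- 1
  if (nseg %% 2 == 0) scale2[nhalf + 1] <- 1   # Nyquist bin not doubled
  dens <- dens * scale2
  out <- tibble(frequency = freq, density = dens)
  structure(out, class = c("spectral_result", class(out)),
            fs = rec$fs, n_segments = count, variance = var(allx))
}

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Integrated band power from a spectral density
#'
#' Trapezoidal integral of the one-sided density over `[lo, hi]`, with the
#' density linearly interpolated at the band edges so that contiguous bands
#' partition the total power exactly.
#'
#' @param spec A `spectral_result` from [welch_psd()].
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @return Band power (signal-units^2).
#' @export
band_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "spectral_result"))
  fs <- attr(spec, "fs")
  if (!(lo >= 0 && lo < hi && hi <= fs / 2 + 1e-9)) {
    abort("band must satisfy 0 <= lo < hi <= fs/2")
  }
  f <- spec$frequency; d <- spec$density
  inside <- f > lo & f < hi
  xf <- c(lo, f[inside], hi)
  yf <- c(approx(f, d, lo, rule = 2)$y, d[inside], approx(f, d, hi, rule = 2)$y)
  trapz_(xf, yf)
}

#' Morlet continuous-wavelet scalogram
#'
#' Time-frequency magnitude matrix from an analytic Morlet wavelet
#' (centre frequency `omega0 = 6`), computed per frequency via FFT
#' convolution.
#'
#' @param rec A [signal_recording()] or numeric vector with `fs`.
#' @param freqs Frequency grid in Hz (default 1-200 Hz in 1 Hz steps); must
#'   lie inside the Nyquist range.
#' @param fs Sampling rate when `rec` is a bare vector.
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @return A list of class `cwt_result`: `magnitude` (freqs x time matrix),
#'   `freqs`, `fs`.
#' @export
cwt_spectrogram <- function(rec, freqs = 1:200, fs = NULL, omega0 = 6) {
  if (is.numeric(rec)) rec <- signal_recording(rec, fs %||% abort("`fs` required"))
  stopifnot(inherits(rec, "signal_recording"))
  if (any(freqs <= 0) || any(freqs >= rec$fs / 2)) {
    abort("frequency grid must lie inside (0, fs/2)")
  }
  x <- rec$samples
  n <- length(x)
  X <- fft(x)
  ang <- 2 * pi * (seq_len(n) - 1) / n           # digital angular frequency
  ang[ang > pi] <- ang[ang > pi] - 2 * pi        # wrap to (-pi, pi]
  mag <- matrix(NA_real_, length(freqs), n)
  for (k in seq_along(freqs)) {
    a <- omega0 * rec$fs / (2 * pi * freqs[k])   # scale in samples
    psi <- ifelse(ang > 0, exp(-0.5 * (a * ang - omega0)^2), 0)
    w <- fft(X * psi * sqrt(a), inverse = TRUE) / n
    mag[k, ] <- Mod(w)
  }
  structure(list(magnitude = mag, freqs = freqs, fs = rec$fs), class = "cwt_result")
}

#' Group comparison of EMG band power
#'
#' For each animal, wake samples are extracted, the Welch density is
#' estimated, and power is integrated over each band; a two-sample t-test
#' (animal as the experimental unit, group A minus group B) then compares
#' the groups per band.
#'
#' @param group_a,group_b Lists of [signal_recording()] objects, at least 2
#'   per group.
#' @param bands Data frame with columns `lo`, `hi` (Hz); defaults to the
#'   20-150, 20-50 and 50-150 Hz motor bands.
#' @param wake_only Analyse wake samples only (default `TRUE`).
#' @param segment_s,overlap Welch parameters, see [welch_psd()].
#' @param log_power Test log10 band power instead of raw power (default
#'   `TRUE`; power ratios are multiplicative).
#' @return A tibble with one row per band: `lo`, `hi`, `mean_a`, `mean_b`
#'   (raw power means), `ratio`, `t`, `p`.
#' @export
group_band_compare <- function(group_a, group_b,
                               bands = data.frame(lo = c(20, 20, 50),
                                                  hi = c(150, 50, 150)),
                               wake_only = TRUE, segment_s = 4.0, overlap = 0.5,
                               log_power = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("need at least 2 animals per group")
  }
  powers <- function(recs) {
    p <- vapply(recs, function(r) {
      if (wake_only) r <- extract_wake(r)
      sp <- welch_psd(r, segment_s = segment_s, overlap = overlap)
      vapply(seq_len(nrow(bands)),
             function(b) band_power(sp, bands$lo[b], bands$hi[b]), numeric(1))
    }, numeric(nrow(bands)))
    # vapply collapses a single band to a plain vector; keep bands x animals
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    t(p)
  }
  pa <- powers(group_a); pb <- powers(group_b)
  ta <- if (log_power) log10(pa) else pa
  tb <- if (log_power) log10(pb) else pb
  tt <- two_sample_t_cols(ta, tb, "student")
  tibble(lo = bands$lo, hi = bands$hi,
         mean_a = colMeans(pa), mean_b = colMeans(pb),
         ratio = colMeans(pa) / colMeans(pb),
         t = tt$t, p = tt$p)
}

#' Mains notch filter
#'
#' Second-order Butterworth band-stop around the mains frequency, applied
#' forward-backward (zero phase).  The default notch (50 Hz +/- 2 Hz)
#' removes mains interference while leaving the 50-150 Hz analysis band
#' essentially intact.
#'
#' @param rec A [signal_recording()].
#' @param freq Notch centre frequency in Hz (default 50).
#' @param width Half-width of the stop band in Hz (default 2).
#' @return The filtered [signal_recording()].
#' @export
notch_filter <- function(rec, freq = 50, width = 2) {
  stopifnot(inherits(rec, "signal_recording"))
  ny <- rec$fs / 2
  bf <- signal::butter(2, c(freq - width, freq + width) / ny, type = "stop")
  out <- rec
  out$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  out
}
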