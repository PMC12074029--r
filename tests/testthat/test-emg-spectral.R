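test_that("simulate_emg honours its spec arithmetic and degenerate cases", {
  spec <- emg_spec(fs = 1000, duration_s = 300, seed = 1)
  rec <- simulate_emg(spec)
  expect_identical(length(rec$samples), 300000L)   # fs * duration
  silent <- emg_spec(duration_s = 5,
                     bands = data.frame(lo = 2, hi = 20, gain = 0),
                     mains_amp = 0, seed = 2)
  expect_true(all(simulate_emg(silent)$samples == 0))
  expect_error(emg_spec(duration_s = 0.5), "2 cycles")
  expect_error(emg_spec(bands = data.frame(lo = 100, hi = 600, gain = 1)),
               "fs/2")
})

test_that("extract_wake keeps exactly the wake runs with correct boundaries", {
  x <- seq_len(100)
  state <- rep(c("wake", "sleep", "wake", "sleep"), each = 25)
  rec <- signal_recording(x, fs = 10, state = state)
  w <- extract_wake(rec)
  expect_identical(w$samples, as.numeric(c(1:25, 51:75)))
  # run-length oracle: segments must match the label runs exactly
  expect_identical(attr(w, "segments")$start, c(1L, 26L))
  expect_identical(attr(w, "segments")$end, c(25L, 50L))
  all_wake <- signal_recording(x, 10)
  expect_identical(extract_wake(all_wake)$samples, as.numeric(x))
  expect_error(extract_wake(signal_recording(x, 10, rep("sleep", 100))),
               "no wake")
})

test_that("rms_envelope recovers closed-form amplitudes", {
  fs <- 100
  const <- signal_recording(rep(-3, 500), fs)
  expect_equal(rms_envelope(const, 1), rep(3, 5))
  # sine of amplitude A over whole cycles -> A / sqrt(2)
  t_s <- seq(0, 10 - 1 / fs, by = 1 / fs)
  sine <- signal_recording(2.5 * sin(2 * pi * 5 * t_s), fs)
  expect_equal(rms_envelope(sine, 1), rep(2.5 / sqrt(2), 10), tolerance = 1e-6)
  expect_equal(rms_envelope(signal_recording(rep(0, 200), fs), 1), rep(0, 2))
  expect_error(rms_envelope(signal_recording(rnorm(10), fs), 1), "longer")
  # windows never straddle wake gaps
  state <- rep(c("wake", "sleep"), each = 150)
  gappy <- extract_wake(signal_recording(rnorm(300), fs, state))
  expect_length(rms_envelope(gappy, 1), 1L)
})

test_that("RMS of equal-length windows composes quadratically", {
  set.seed(14)
  x <- rnorm(400)
  rec <- signal_recording(x, 100)
  env <- rms_envelope(rec, 1)   # 4 windows of 100
  expect_equal(sqrt(mean(env^2)), sqrt(mean(x^2)), tolerance = 1e-12)
})

test_that("amplitude_stats summarises the envelope", {
  s <- amplitude_stats(c(1, 2, 3))
  expect_equal(s$max, 3)
  expect_equal(s$mean, 2)
  s2 <- amplitude_stats(2 * c(1, 2, 3))
  expect_equal(c(s2$max, s2$mean), 2 * c(s$max, s$mean))
  expect_error(amplitude_stats(numeric()), "empty")
})

test_that("welch_psd localises tones and satisfies Parseval", {
  fs <- 1000
  t_s <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tone <- signal_recording(sin(2 * pi * 100 * t_s), fs)
  sp <- welch_psd(tone)
  expect_equal(sp$frequency[which.max(sp$density)], 100, tolerance = 0.25)
  set.seed(15)
  noise <- signal_recording(rnorm(length(t_s), sd = 1.7), fs)
  spn <- welch_psd(noise)
  total <- band_power(spn, 0, fs / 2)
  expect_equal(total, attr(spn, "variance"), tolerance = 0.05 * attr(spn, "variance"))
  zero <- welch_psd(signal_recording(rep(0, 8000), fs))
  expect_true(all(zero$density == 0))
  expect_error(welch_psd(signal_recording(rnorm(100), fs)), "shorter")
  # constant offsets are removed before the transform
  sp_off <- welch_psd(signal_recording(noise$samples + 100, fs))
  expect_equal(sp_off$density, spn$density, tolerance = 1e-9)
})

test_that("band_power integrates the density additively", {
  fs <- 1000
  t_s <- seq(0, 16 - 1 / fs, by = 1 / fs)
  sp <- welch_psd(signal_recording(sin(2 * pi * 100 * t_s), fs))
  total <- band_power(sp, 0, 500)
  expect_gt(band_power(sp, 50, 150) / total, 0.95)   # leakage-bounded
  parts <- band_power(sp, 0, 20) + band_power(sp, 20, 50) +
    band_power(sp, 50, 150) + band_power(sp, 150, 500)
  expect_equal(parts, total, tolerance = 1e-9)
  expect_error(band_power(sp, 400, 600), "fs/2")
  zero_sp <- welch_psd(signal_recording(rep(0, 8000), fs))
  expect_equal(band_power(zero_sp, 20, 150), 0)
})

test_that("band power scales with the squared synthetic gain", {
  mk <- function(g, s) simulate_emg(emg_spec(
    duration_s = 30, bands = data.frame(lo = 50, hi = 150, gain = g),
    mains_amp = 0, wake_fraction = 1, seed = s))
  p1 <- vapply(1:5, function(s) band_power(welch_psd(mk(1, s)), 50, 150), numeric(1))
  p2 <- vapply(1:5, function(s) band_power(welch_psd(mk(2, s + 50)), 50, 150), numeric(1))
  expect_equal(mean(p2) / mean(p1), 4, tolerance = 0.15)
})

test_that("Morlet scalogram ridges track tone and chirp frequencies", {
  fs <- 500
  t_s <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone <- cwt_spectrogram(signal_recording(sin(2 * pi * 60 * t_s), fs),
                          freqs = seq(10, 150, by = 5))
  interior <- seq(200, length(t_s) - 200)  # avoid edge effects
  ridge <- tone$freqs[apply(tone$magnitude[, interior], 2, which.max)]
  expect_true(all(abs(ridge - 60) <= 5))
  # linear chirp 20 -> 120 Hz: instantaneous frequency tracked
  f0 <- 20; f1 <- 120
  chirp <- sin(2 * pi * (f0 * t_s + (f1 - f0) / (2 * max(t_s)) * t_s^2))
  cw <- cwt_spectrogram(signal_recording(chirp, fs), freqs = seq(10, 150, by = 5))
  inst <- f0 + (f1 - f0) * t_s / max(t_s)
  ridge2 <- cw$freqs[apply(cw$magnitude[, interior], 2, which.max)]
  expect_lt(median(abs(ridge2 - inst[interior])), 10)
  z <- cwt_spectrogram(signal_recording(rep(0, 500), fs), freqs = c(10, 50))
  expect_true(all(z$magnitude == 0))
})

test_that("group_band_compare flags identical groups as null and flips with labels", {
  set.seed(16)
  recs <- lapply(1:3, function(s) simulate_emg(emg_spec(duration_s = 10, seed = s)))
  same <- group_band_compare(recs, recs)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  recs2 <- lapply(4:6, function(s) simulate_emg(emg_spec(
    duration_s = 10, bands = data.frame(lo = 50, hi = 150, gain = 2), seed = s)))
  ab <- group_band_compare(recs, recs2)
  ba <- group_band_compare(recs2, recs)
  expect_equal(ab$t, -ba$t, tolerance = 1e-10)
  expect_error(group_band_compare(recs[1], recs), "at least 2")
})

test_that("the mains notch removes a 50 Hz tone but spares the band", {
  fs <- 1000
  t_s <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 50 * t_s) + 0.5 * sin(2 * pi * 120 * t_s)
  filt <- notch_filter(signal_recording(x, fs))
  sp <- welch_psd(filt)
  expect_lt(band_power(sp, 48, 52), 0.01)
  expect_equal(band_power(sp, 110, 130), 0.125, tolerance = 0.02)
})
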