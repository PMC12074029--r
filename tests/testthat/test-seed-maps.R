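dim3 <- c(12, 12, 8)

test_that("seed_timecourse is the unweighted voxel mean", {
  set.seed(17)
  vol <- array(rnorm(prod(dim3) * 20), c(dim3, 20))
  one <- cube_mask(dim3, c(3, 3, 3), 0)
  expect_equal(seed_timecourse(vol, one), vol[3, 3, 3, ])
  # a(t) and -a(t) average to zero
  vol2 <- vol
  vol2[5, 5, 5, ] <- -vol2[4, 5, 5, ]
  two <- array(FALSE, dim3); two[4:5, 5, 5] <- TRUE
  expect_equal(seed_timecourse(vol2, two), rep(0, 20))
  expect_error(seed_timecourse(vol, array(FALSE, dim3)), "empty")
})

test_that("seed_correlation_map recovers exact and planted correlations", {
  set.seed(18)
  seed_m <- cube_mask(dim3, c(3, 3, 4), 0)
  region <- cube_mask(dim3, c(9, 9, 5), 1)
  v <- simulate_voxel_volume(dim3, 300, seed_m, region, target_corr = 0.8, seed = 4)
  tc <- seed_timecourse(v, seed_m)
  m <- seed_correlation_map(v, tc)
  # the seed voxel itself correlates at 1 with its own (single-voxel) mean
  expect_equal(m$map[3, 3, 4], 1, tolerance = 1e-12)
  expect_equal(mean(m$map[region]), 0.8, tolerance = 0.1)
  # null voxels: |r| < 0.2 for >= 95% at 300 timepoints
  bg <- m$map[!region & !seed_m]
  expect_gt(mean(abs(bg) < 0.2), 0.95)
  expect_error(seed_correlation_map(v, rep(1, 300)), "constant")
  expect_error(seed_correlation_map(v, rnorm(10)), "length")
})

test_that("correlation maps are invariant to affine intensity rescaling", {
  set.seed(19)
  seed_m <- cube_mask(dim3, c(3, 3, 4), 0)
  v <- simulate_voxel_volume(dim3, 50, seed_m, NULL, seed = 5)
  tc <- seed_timecourse(v, seed_m)
  m1 <- seed_correlation_map(v, tc)
  v$data <- 3.2 * v$data + 7
  m2 <- seed_correlation_map(v, 3.2 * tc + 7)
  expect_equal(m1$map, m2$map, tolerance = 1e-10)
})

test_that("group t-maps vanish for identical groups and negate under label swap", {
  set.seed(20)
  seed_m <- cube_mask(dim3, c(3, 3, 4), 0)
  mk <- function(s, rho) {
    v <- simulate_voxel_volume(dim3, 60, seed_m, cube_mask(dim3, c(9, 9, 5), 1),
                               target_corr = rho, seed = s)
    seed_correlation_map(v, seed_timecourse(v, seed_m), domain = "z")
  }
  a <- lapply(1:3, mk, rho = 0.7)
  b <- lapply(4:6, mk, rho = 0.2)
  same <- group_seed_tmap(a, a)
  expect_true(all(same$t[!is.na(same$t)] == 0))
  ab <- group_seed_tmap(a, b)
  ba <- group_seed_tmap(b, a)
  expect_equal(ab$t, -ba$t, tolerance = 1e-10)
  small <- lapply(a, function(m) { m$map <- m$map[1:6, , ]; m })
  expect_error(group_seed_tmap(small, b), "mismatch")
})

test_that("ROI-level and voxel-level pipelines agree on shared synthetic data", {
  set.seed(22)
  seed_m <- cube_mask(dim3, c(3, 3, 4), 1)
  region <- cube_mask(dim3, c(9, 9, 5), 1)
  # spatially shared region noise emulates smoothed data, under which the
  # two averaging orders coincide
  v <- simulate_voxel_volume(dim3, 200, seed_m, region, target_corr = 0.6,
                             seed = 6, noise_share = 0.9)
  tc_seed <- seed_timecourse(v, seed_m)
  tc_region <- seed_timecourse(v, region)
  roi_r <- unclass(pearson_fc(cbind(a = tc_seed, b = tc_region)))[1, 2]
  vox_mean_r <- mean(seed_correlation_map(v, tc_seed)$map[region])
  expect_lt(abs(vox_mean_r - roi_r), 0.1)
})

test_that("overlapping seed and region masks require an explicit flag", {
  m <- cube_mask(dim3, c(5, 5, 5), 1)
  expect_error(simulate_voxel_volume(dim3, 20, m, m, 0.5, seed = 1), "overlap")
  expect_s3_class(simulate_voxel_volume(dim3, 20, m, m, 0.5, seed = 1,
                                        allow_overlap = TRUE), "voxel_series")
})

test_that("NIfTI round trip preserves voxel data", {
  a <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(a, f)
  b <- read_nifti(f)
  expect_equal(as.numeric(b), as.numeric(a), tolerance = 1e-6)
  unlink(f)
})
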