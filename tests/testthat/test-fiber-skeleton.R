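test_that("binarize separates two-level images exactly and passes booleans", {
  b <- matrix(c(TRUE, FALSE), 4, 4)
  expect_identical(binarize(b), b)
  g <- matrix(0, 10, 10); g[3:7, 3:7] <- 255
  out <- binarize(g)
  expect_true(all(out == (g == 255)))
  expect_error(binarize(matrix(5, 3, 3)), "constant")
})

test_that("binarize recovers rendered curves from noisy grayscale", {
  sim <- simulate_fiber_image(10, 120, c(128, 128), seed = 41)
  set.seed(41)
  noisy <- sim$image * 1 + matrix(rnorm(length(sim$image), 0, 0.2), nrow(sim$image))
  rec <- binarize(noisy)
  expect_gt(dice_overlap(rec, sim$image), 0.9)
})

test_that("a straight 100-pixel line measures 99 with no branch points", {
  img <- matrix(FALSE, 110, 20)
  img[6:105, 10] <- TRUE
  sm <- skeleton_metrics(img, pixel_size_um = 1)
  expect_equal(sm$total_length_um, 99)
  expect_identical(sm$n_branch_points, 0L)
  # two endpoints, both degree 1
  expect_identical(sort(sm$graph$nodes$degree), c(1L, 1L))
  dd <- node_degree_density(sm)
  expect_identical(dd$degree, 1L)
  expect_equal(dd$density, 1)
  # diagonal line: sqrt(2) steps
  dg <- matrix(FALSE, 30, 30)
  dg[cbind(5:25, 5:25)] <- TRUE
  expect_equal(skeleton_metrics(dg)$total_length_um, 20 * sqrt(2))
})

test_that("the plus-cross fixture has one degree-4 junction", {
  img <- cross_image(31)
  sm <- skeleton_metrics(img)
  expect_identical(sm$n_branch_points, 1L)
  jn <- sm$graph$nodes[sm$graph$nodes$type == "junction", ]
  expect_identical(jn$degree, 4L)
  dd <- node_degree_density(sm)
  expect_equal(dd$density[dd$degree == 1], 0.8)
  expect_equal(dd$density[dd$degree == 4], 0.2)
  expect_equal(sum(dd$density), 1)
})

test_that("skeleton length is invariant to rotation and reflection", {
  sim <- simulate_fiber_image(5, 80, c(96, 96), seed = 42)
  base <- skeleton_metrics(sim$image)
  rotated <- skeleton_metrics(t(sim$image)[ncol(sim$image):1, ])   # 90 degrees
  mirrored <- skeleton_metrics(sim$image[, ncol(sim$image):1])
  # thinning deletion order is slightly orientation-dependent, so invariance
  # is tight but not exact
  expect_equal(rotated$total_length_um, base$total_length_um, tolerance = 0.01)
  expect_equal(mirrored$total_length_um, base$total_length_um, tolerance = 0.01)
  expect_lte(abs(rotated$n_branch_points - base$n_branch_points), 1)
})

test_that("thinning is idempotent and length scales with pixel size", {
  sim <- simulate_fiber_image(6, 90, c(96, 96), seed = 43)
  sm1 <- skeleton_metrics(sim$image)
  sm2 <- skeleton_metrics(sm1$skeleton)
  expect_identical(sm2$skeleton, sm1$skeleton)
  expect_equal(sm2$total_length_um, sm1$total_length_um)
  sm_px <- skeleton_metrics(sim$image, pixel_size_um = 0.31)
  expect_equal(sm_px$total_length_um, 0.31 * sm1$total_length_um, tolerance = 1e-9)
})

test_that("skeleton length matches the generator's analytic ground truth", {
  sim <- simulate_fiber_image(20, 150, c(256, 256), seed = 44)
  sm <- skeleton_metrics(sim$image)
  expect_equal(sm$total_length_um, sim$length_px, tolerance = 0.1 * sim$length_px)
})

test_that("the generator validates sizes and reproduces under a fixed seed", {
  expect_error(simulate_fiber_image(100, 10000, c(32, 32)), "too small")
  s1 <- simulate_fiber_image(3, 40, c(64, 64), seed = 9)
  s2 <- simulate_fiber_image(3, 40, c(64, 64), seed = 9)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$length_px, s2$length_px)
  expect_error(skeleton_metrics(matrix(FALSE, 5, 5)), "empty")
})
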