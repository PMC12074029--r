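test_that("circular-equivalent diameter matches its closed form", {
  expect_equal(circ_equiv_diameter(pi), 2)
  expect_equal(circ_equiv_diameter(0), 0)
  expect_equal(circ_equiv_diameter(31415.93), 200, tolerance = 1e-6)
  expect_error(circ_equiv_diameter(-1), "non-negative")
})

test_that("g_ratio computes, bounds, and rejects correctly", {
  expect_equal(g_ratio(200, 250), 0.8)
  # scale invariance
  expect_equal(g_ratio(200 * 3.5, 250 * 3.5), 0.8, tolerance = 1e-12)
  # unmyelinated limit: g -> 1 from below
  expect_lt(g_ratio(250 - 1e-9, 250), 1)
  expect_warning(g <- g_ratio(c(200, 300), c(250, 250)), "1 row")
  expect_true(is.na(g[2]))
})

test_that("areas and diameters give algebraically identical g", {
  set.seed(24)
  a_in <- runif(50, 1e4, 5e4)
  a_out <- a_in * runif(50, 1.2, 3)
  g_from_d <- g_ratio(circ_equiv_diameter(a_in), circ_equiv_diameter(a_out))
  expect_equal(g_from_d, sqrt(a_in / a_out), tolerance = 1e-12)
  # table path accepts areas
  tab <- tibble::tibble(group = "control", inner_area_nm2 = a_in, outer_area_nm2 = a_out)
  tr <- gratio_diameter_trend(tab)
  expect_identical(tr$n, 50L)
})

test_that("stratified comparison handles identical groups and label swaps", {
  set.seed(25)
  base <- simulate_axons(axon_spec(n_axons = 80, seed = 3), "control")
  dup <- dplyr::mutate(base, group = "treated")
  res <- stratified_compare(dplyr::bind_rows(base, dup))
  expect_true(all(res$delta == 0))
  expect_true(all(res$p == 1))
  other <- simulate_axons(axon_spec(n_axons = 80, seed = 9), "treated")
  ab <- stratified_compare(dplyr::bind_rows(base, other))
  swapped <- dplyr::bind_rows(dplyr::mutate(base, group = "treated"),
                              dplyr::mutate(other, group = "control"))
  ba <- stratified_compare(swapped)
  expect_equal(ab$t, -ba$t, tolerance = 1e-10)
})

test_that("a threshold beyond all diameters leaves a single populated stratum", {
  set.seed(26)
  tab <- dplyr::bind_rows(simulate_axons(axon_spec(n_axons = 40, seed = 1), "control"),
                          simulate_axons(axon_spec(n_axons = 40, seed = 2), "treated"))
  res <- stratified_compare(tab, threshold_nm = 1e9)
  expect_identical(res$stratum, "below")
})

test_that("the OLS trend recovers exact and degenerate fits", {
  d <- seq(100, 900, by = 50)
  tab <- tibble::tibble(group = "control", inner_nm = d,
                        outer_nm = d / (0.0002 * d + 0.6))
  # noiseless fits trip lm's perfect-fit warning; that is the point here
  tr <- suppressWarnings(gratio_diameter_trend(tab))
  expect_equal(tr$slope, 0.0002, tolerance = 1e-10)
  expect_equal(tr$intercept, 0.6, tolerance = 1e-10)
  flat <- tibble::tibble(group = "control", inner_nm = d, outer_nm = d / 0.7)
  expect_equal(suppressWarnings(gratio_diameter_trend(flat))$slope, 0,
               tolerance = 1e-10)
  same_d <- tibble::tibble(group = "control", inner_nm = rep(300, 5),
                           outer_nm = rep(400, 5))
  expect_error(gratio_diameter_trend(same_d), "variance")
})

test_that("simulated axons respect construction invariants", {
  spec <- axon_spec(n_axons = 300, seed = 30)
  for (g in c("control", "treated")) {
    tab <- simulate_axons(spec, g)
    expect_true(all(tab$inner_nm < tab$outer_nm))
    expect_true(all(tab$inner_nm > 0))
  }
  # no shift -> group means agree within sampling error
  null_spec <- axon_spec(n_axons = 400, gratio_shift = 0, seed = 31)
  a <- simulate_axons(null_spec, "treated")
  b <- simulate_axons(axon_spec(n_axons = 400, gratio_shift = 0, seed = 32), "control")
  res <- stratified_compare(dplyr::bind_rows(a, b))
  expect_true(all(abs(res$delta) < 0.02))
  expect_error(axon_spec(gratio_baseline = 0.99), "outside")
})

test_that("a planted positive slope has its sign recovered reliably", {
  signs <- vapply(1:40, function(s) {
    tab <- simulate_axons(axon_spec(n_axons = 500, gratio_slope_per_nm = 1e-4,
                                    seed = 100 + s), "control")
    sign(gratio_diameter_trend(tab)$slope)
  }, numeric(1))
  expect_gte(mean(signs == 1), 0.95)
})
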