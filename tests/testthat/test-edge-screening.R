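test_that("identical groups give t = 0 and p = 1 at every edge", {
  set.seed(3)
  mats <- random_z_mats(3, 5)   # same animals duplicated into both groups
  res <- edgewise_ttest(mats, mats)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_identical(nrow(res), 10L)
  # truly constant edges have zero pooled variance and are flagged
  const <- z_mats_one_edge(c(0.2, 0.2))
  expect_warning(res0 <- edgewise_ttest(const, const), "zero pooled variance")
  expect_true(all(res0$p == 1))
})

test_that("edge-wise t and p match stats::t.test and the pooled formula", {
  a_vals <- c(0.1, 0.2, 0.3)
  b_vals <- c(0.4, 0.5, 0.6)
  # the fixture's untouched edges are all-zero, hence the variance warning
  res <- suppressWarnings(edgewise_ttest(z_mats_one_edge(a_vals), z_mats_one_edge(b_vals)))
  row <- res[res$i == 1 & res$j == 2, ]
  ref <- t.test(a_vals, b_vals, var.equal = TRUE)
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  expect_equal(row$t, oracle_pooled_t(a_vals, b_vals), tolerance = 1e-12)
  expect_equal(row$d, oracle_cohens_d(a_vals, b_vals), tolerance = 1e-12)
  # Welch variant agrees with stats::t.test too
  set.seed(8)
  av <- rnorm(4, 0, 0.2); bv <- rnorm(5, 0.3, 0.05)
  resw <- suppressWarnings(edgewise_ttest(z_mats_one_edge(av), z_mats_one_edge(bv),
                                          screen_config(test_variant = "welch")))
  refw <- t.test(av, bv)
  roww <- resw[resw$i == 1 & resw$j == 2, ]
  expect_equal(roww$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(roww$p, refw$p.value, tolerance = 1e-12)
})

test_that("31 ROIs yield 465 edge records", {
  set.seed(4)
  res <- edgewise_ttest(random_z_mats(2, 31), random_z_mats(2, 31))
  expect_identical(nrow(res), 465L)
  expect_true(all(res$i < res$j))
  expect_false(any(duplicated(res[, c("i", "j")])))
})

test_that("p-value adjustment matches brute-force oracles and is monotone", {
  expect_equal(adjust_pvalues(1), 1)
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)  # m = 1
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh_fdr"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(5)
  for (rep_i in 1:20) {
    p <- runif(50)
    adj <- adjust_pvalues(p, "bh_fdr")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # monotonicity: raising one raw p never lowers any adjusted p
    p2 <- p
    k <- sample(50, 1)
    p2[k] <- min(1, p2[k] + runif(1, 0, 1 - p2[k]))
    expect_true(all(adjust_pvalues(p2, "bh_fdr") >= adj - 1e-12))
  }
})

test_that("Cohen's D matrix handles nulls, degeneracy, and symmetry", {
  a <- z_mats_one_edge(c(0.2, 0.2))
  expect_warning(D <- cohens_d_matrix(a, a), "zero pooled SD")
  expect_true(all(is.na(D) | D == 0))
  set.seed(6)
  ga <- random_z_mats(4, 6); gb <- random_z_mats(4, 6)
  D2 <- cohens_d_matrix(ga, gb)
  expect_equal(D2, t(D2))
  expect_true(all(is.na(diag(D2))))
  za <- t(sapply(ga, function(m) unclass(m)[1, 2]))
  expect_equal(D2[1, 2],
               oracle_cohens_d(sapply(ga, function(m) unclass(m)[1, 2]),
                               sapply(gb, function(m) unclass(m)[1, 2])),
               tolerance = 1e-12)
})

test_that("swapping group labels negates t and D and leaves p unchanged", {
  set.seed(9)
  ga <- random_z_mats(4, 6); gb <- random_z_mats(5, 6)
  r1 <- edgewise_ttest(ga, gb)
  r2 <- edgewise_ttest(gb, ga)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)
  expect_equal(r1$d, -r2$d, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("screen_edges partitions edges into the documented sets", {
  set.seed(10)
  ga <- random_z_mats(5, 8); gb <- random_z_mats(5, 8)
  res <- edgewise_ttest(ga, gb)
  scr <- screen_edges(res, screen_config(alpha = 0.9999, d_threshold = 1e-6))
  expect_identical(nrow(scr$intersection),
                   nrow(dplyr::semi_join(scr$significance, scr$effect, by = c("i", "j"))))
  # all p_adj forced irrelevant -> empty sets at tiny alpha / huge threshold
  scr0 <- screen_edges(res, screen_config(alpha = 1e-12, d_threshold = 1e6))
  expect_identical(nrow(scr0$significance), 0L)
  expect_identical(nrow(scr0$effect), 0L)
  expect_identical(nrow(scr0$intersection), 0L)
  g <- glance(scr0)
  expect_identical(g$n_significant, 0L)
})

test_that("degenerate single-animal groups are refused", {
  m <- random_z_mats(1, 4)
  expect_error(edgewise_ttest(m, m), "at least 2")
})
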