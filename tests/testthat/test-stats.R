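test_that("Gini matches hand-derived values and the double-sum oracle", {
  expect_equal(gini_unbiased(c(5, 5, 5, 5)), 0)
  expect_equal(gini_unbiased(c(0, 1)), 1)
  expect_equal(gini_unbiased(c(1, 2, 3)), 1 / 3)
  expect_true(is.na(gini_unbiased(c(0, 0, 0))))
  set.seed(17)
  for (i in 1:50) {
    x <- stats::rgamma(sample(2:50, 1), shape = 0.8) * 10
    expect_equal(gini_unbiased(x), gini_oracle(x), tolerance = 1e-12)
    expect_equal(gini_unbiased(7.3 * x), gini_unbiased(x), tolerance = 1e-12)
  }
})

test_that("relative Gini change handles both directions and zero controls", {
  expect_equal(delta_gini(0.2, 0.4), list(rel_change = 1, ratio = 2))
  expect_equal(delta_gini(0.3, 0.3), list(rel_change = 0, ratio = 1))
  expect_equal(delta_gini(0.4, 0.1), list(rel_change = -0.75, ratio = 0.25))
  expect_true(all(is.na(unlist(delta_gini(0, 0.3)))))
})

test_that("NB test is null-calibrated on identity and powered on real shifts", {
  x <- c(10, 12, 9, 11, 10, 13)
  r <- nb_test(x, x)
  expect_gt(r$p_value, 0.9)
  expect_equal(r$fold_change, 1, tolerance = 1e-9)
  expect_equal(nb_test(rep(0, 6), rep(0, 8))$p_value, 1)
  # 4x mean shift at moderate dispersion: decisively detected
  set.seed(3)
  ctrl <- matrix(rnbinom(100 * 12, mu = 50, size = 20), 100, 12)
  case <- matrix(rnbinom(100 * 46, mu = 200, size = 20), 100, 46)
  p <- nb_test_many(ctrl, case)$p_value
  expect_gte(mean(p < 1e-6), 0.99)
  # fold change uses 0.5 pseudocounts on group means
  r2 <- nb_test(c(0, 0, 0, 0), c(3, 5, 4, 4))
  expect_equal(r2$fold_change, 4.5 / 0.5)
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 5)), rep(0.05, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.01, 0.04, 0.8)
  expect_equal(bh_adjust(p), c(0.004, 0.02, 0.04 * 4 / 3, 0.8))
})

test_that("min-rescaling normalizes to 1 with the +1 zero guard", {
  expect_equal(rescale_by_min(c(10, 20, 40)), c(1, 2, 4))
  expect_equal(rescale_by_min(c(0, 3, 9)), c(1, 4, 10))
  expect_equal(rescale_by_min(7), 1)
  expect_true(all(is.na(rescale_by_min(c(0, 3), zero_guard = FALSE))))
})

test_that("exon:intron correlation matches the textbook formula", {
  e <- c(3, 9, 1, 7, 2, 8)
  expect_equal(exon_intron_correlation(e, 2 * e), 1)
  expect_equal(exon_intron_correlation(e, -e + 100), -1)
  i <- c(5, 1, 9, 2, 7, 4)
  manual <- sum((e - mean(e)) * (i - mean(i))) /
    sqrt(sum((e - mean(e))^2) * sum((i - mean(i))^2))
  expect_equal(exon_intron_correlation(e, i), manual, tolerance = 1e-12)
  expect_true(is.na(exon_intron_correlation(rep(2, 5), i[1:5])))
  expect_equal(exon_intron_correlation(e, i, method = "spearman"),
               stats::cor(rank(e), rank(i)), tolerance = 1e-12)
})

test_that("Fisher z correlation differential follows the closed form", {
  expect_equal(correlation_differential(0.5, 10, 0.5, 20)$p_value, 1)
  # the r = 0.89 (n=12) vs r = 0.33 (n=46) contrast, against an
  # independently coded normal-CDF oracle
  res <- correlation_differential(0.89, 12, 0.33, 46)
  z_o <- (0.5 * log(1.89 / 0.11) - 0.5 * log(1.33 / 0.67)) /
    sqrt(1 / 9 + 1 / 43)
  expect_equal(res$statistic, z_o, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * (1 - stats::pnorm(abs(z_o))),
               tolerance = 1e-10)
  # growing equal n makes the p-value monotone non-increasing
  ps <- vapply(c(5, 10, 20, 40, 80),
               function(n) correlation_differential(0.6, n, 0.3, n)$p_value,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_warning(correlation_differential(1, 10, 0.5, 10), "clipped")
})

test_that("robust slope resists outliers and fixes the intercept at zero", {
  x <- seq(1, 10, length.out = 20)
  r <- robust_slope(x, 3 * x)
  expect_equal(r$slope, 3, tolerance = 1e-9)
  expect_lt(r$se, 1e-9)
  set.seed(12)
  y <- 2 * x
  y[1:4] <- y[1:4] + c(30, -25, 40, 35)  # 20% gross outliers
  expect_equal(robust_slope(x, y)$slope, 2, tolerance = 0.05)
  expect_equal(robust_slope(x, rep(0, 20))$slope, 0)
  expect_error(robust_slope(rep(1, 5), 1:5), "degenerate")
})

test_that("slope difference test matches its normal oracle", {
  expect_equal(slope_difference_test(2, 0.1, 2, 0.2), 1)
  expect_lt(slope_difference_test(10, 0.01, 1, 0.01), 1e-10)
  set.seed(8)
  for (i in 1:20) {
    s1 <- rnorm(1); s2 <- rnorm(1)
    se1 <- runif(1, 0.05, 1); se2 <- runif(1, 0.05, 1)
    t <- (s1 - s2) / sqrt(se1^2 + se2^2)
    expect_equal(slope_difference_test(s1, se1, s2, se2),
                 2 * stats::pnorm(-abs(t)), tolerance = 1e-12)
  }
})
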