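test_that("stratified summary reports the standard five statistics", {
  s <- stratified_summary(rep(7, 10))
  expect_equal(s$mean, 7); expect_equal(s$median, 7); expect_equal(s$sd, 0)
  expect_equal(s$p25, 7); expect_equal(s$p75, 7)

  # linear-interpolation quartiles of 1..5
  s2 <- stratified_summary(1:5)
  expect_equal(s2$median, 3)
  expect_equal(s2$p25, 2)
  expect_equal(s2$p75, 4)

  vals <- c(10, 20, 30, 40)
  strat <- c("f", "f", "m", "m")
  s3 <- stratified_summary(vals, strat)
  expect_equal(s3$stratum, c("f", "m", "total"))
  # pooled mean is the count-weighted combination of strata means
  w <- s3$n[1:2] / sum(s3$n[1:2])
  expect_equal(sum(w * s3$mean[1:2]), s3$mean[3])
  expect_true(all(s3$p25 <= s3$median & s3$median <= s3$p75))
  expect_warning(stratified_summary(c(1, 2), c("a", NA)), "empty")
})

test_that("ICC(3,k) matches an independent ANOVA computation", {
  # hand-built 6x3 matrix
  m <- matrix(c(9, 10, 12,
                6,  8,  7,
                8,  9, 10,
                7,  7,  9,
                10, 12, 13,
                6,  5,  8), nrow = 6, byrow = TRUE)
  res <- icc3k(m)
  # oracle: two-way ANOVA via stats::aov
  df <- data.frame(y = as.vector(m),
                   target = factor(rep(1:6, times = 3)),
                   rater = factor(rep(1:3, each = 6)))
  av <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  ms_t <- av["target", "Mean Sq"]
  ms_e <- av["Residuals", "Mean Sq"]
  expect_equal(res$icc, (ms_t - ms_e) / ms_t, tolerance = 1e-10)
  expect_equal(res$ms_targets, ms_t, tolerance = 1e-10)
  expect_equal(res$ms_error, ms_e, tolerance = 1e-10)
  # the CI brackets the estimate
  expect_lt(res$ci[1], res$icc)
  expect_gt(res$ci[2], res$icc)
})

test_that("ICC(3,k) is consistency-form invariant and bounded", {
  set.seed(5)
  base <- matrix(rpois(40, 60), 10, 4)
  r0 <- icc3k(base)
  # per-rater additive offsets do not change it
  off <- sweep(base, 2, c(0, 5, -3, 10), "+")
  expect_equal(icc3k(off)$icc, r0$icc, tolerance = 1e-12)
  # common rescaling does not change it
  expect_equal(icc3k(base * 3.7)$icc, r0$icc, tolerance = 1e-12)
  # identical raters -> perfect agreement
  perfect <- matrix(rep(rpois(8, 50), 5), ncol = 5)
  expect_equal(icc3k(perfect)$icc, 1)
  expect_equal(icc3k(perfect)$ci, c(1, 1))
  # degenerate inputs are signalled
  expect_error(icc3k(matrix(5, 4, 3)), "zero between-target")
  expect_error(icc3k(matrix(1:4, 4, 1)), "at least 2")
})

test_that("normalized range and the within-range check follow hand arithmetic", {
  expect_equal(normalized_range(c(5, 5, 5)), 0)
  expect_equal(normalized_range(c(4, 5, 6)), 0.4)
  expect_equal(normalized_range(c(8, 10, 12, 10, 10)), 0.4)
  # scale invariance
  expect_equal(normalized_range(7 * c(8, 10, 12, 10, 10)), 0.4)
  expect_error(normalized_range(c(0, 0)), "undefined")

  manual <- c(48, 50, 52, 55, 49)
  expect_true(within_range_check(50, manual, 1))
  expect_true(within_range_check(25, manual, 0.5))   # adjusted to 50
  expect_false(within_range_check(60, manual, 1))
  expect_false(within_range_check(20, manual, 1))
  expect_error(within_range_check(10, manual, 0), "positive")
})

test_that("Pearson matrix matches the from-scratch formula", {
  set.seed(9)
  x <- c(2.1, 3.3, 1.8, 4.4, 5.0, 2.9, 3.7, 4.1, 1.2, 3.0)
  y <- c(1.0, 2.5, 1.1, 3.9, 4.2, 2.2, 3.5, 3.1, 0.4, 2.8)
  z <- rnorm(10)
  pm <- pearson_matrix(data.frame(x = x, y = y, z = z))
  # oracle: direct formula evaluation
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((10 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 8)
  expect_equal(pm$r["x", "y"], r_hand, tolerance = 1e-12)
  expect_equal(pm$p["x", "y"], p_hand, tolerance = 1e-12)
  expect_identical(pm$flag["x", "y"], p_hand < 0.001)

  # structure: symmetry, unit diagonal, affine invariance, exact limits
  expect_equal(pm$r, t(pm$r))
  expect_equal(unname(diag(pm$r)), rep(1, 3))
  pm2 <- pearson_matrix(data.frame(a = x, b = 2 * x + 1))
  expect_equal(pm2$r["a", "b"], 1)
  pm3 <- pearson_matrix(data.frame(a = x, b = -x))
  expect_equal(pm3$r["a", "b"], -1)
  # zero-variance column reported missing
  pm4 <- pearson_matrix(data.frame(a = x, c = rep(2, 10)))
  expect_true(is.na(pm4$r["a", "c"]))
})

test_that("age trend recovers exact and noisy linear declines", {
  age <- seq(25, 75, length.out = 20)
  dens <- 7000 - 11 * age
  tr <- suppressWarnings(age_trend(dens, age))  # exact fit warns in summary()
  expect_equal(tr$slope, -11, tolerance = 1e-10)
  expect_equal(tr$intercept, 7000, tolerance = 1e-8)
  expect_equal(tr$r, -1, tolerance = 1e-10)
  expect_error(age_trend(dens, rep(50, 20)), "degenerate")
  expect_error(age_trend(dens[1:2], age[1:2]), "at least 3")
})
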