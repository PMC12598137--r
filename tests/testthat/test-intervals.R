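test_that("Brunner-Munzel interval: printed example, symmetry, unclipped", {
  d <- demo_metric()
  ci <- bm_interval(d$x, d$y)
  expect_equal(round(ci$lower, 2), 0.55)
  expect_equal(round(ci$upper, 2), 1.05)  # exceeds 1: not range-preserving
  expect_false(ci$range_preserving)
  est <- mw_estimates(d$x, d$y)
  expect_equal((ci$lower + ci$upper) / 2, est$theta, tolerance = 1e-12)
  # alpha -> 1 collapses onto the estimate
  tight <- bm_interval(d$x, d$y, alpha = 1 - 1e-12)
  expect_equal(tight$lower, est$theta, tolerance = 1e-6)
  expect_equal(tight$upper, est$theta, tolerance = 1e-6)
  expect_error(bm_interval(c(1, 2), c(5, 6)), "undefined")
})

test_that("Wilson-type interval: printed example, symmetry at 1/2, asymmetry", {
  d <- demo_metric()
  ci <- c2_interval(d$x, d$y)
  expect_equal(round(ci$lower, 2), 0.53)
  expect_equal(round(ci$upper, 2), 0.93)
  expect_true(ci$range_preserving)
  # theta-hat = 1/2 gives bounds symmetric about 1/2
  set.seed(51)
  x <- rnorm(8); y <- x  # identical samples
  ci2 <- c2_interval(x, y)
  expect_equal(ci2$lower + ci2$upper, 1, tolerance = 1e-12)
  # generally asymmetric about the estimate
  est <- mw_estimates(d$x, d$y)
  expect_false(isTRUE(all.equal((ci$lower + ci$upper) / 2, est$theta)))
})

test_that("Birnbaum-Klose interval boundary forms", {
  cc <- qchisq(0.95, 1)
  ci1 <- bk_interval(1, m = 4)
  expect_equal(ci1$lower, 4 / (4 + cc))
  expect_equal(ci1$upper, 1)
  expect_equal(round(ci1$lower, 3), 0.510)
  ci0 <- bk_interval(0, m = 4)
  expect_equal(ci0$lower, 0)
  expect_equal(ci0$upper, cc / (4 + cc))
  big <- bk_interval(0.5, m = 1e7)
  expect_equal(big$lower, 0.5, tolerance = 1e-3)
  expect_equal(big$upper, 0.5, tolerance = 1e-3)
  expect_error(bk_interval(0.5, m = 1), "at least 2")
})

test_that("range preservation and test compatibility on randomized inputs", {
  set.seed(52)
  for (i in 1:300) {
    inst <- random_instance()
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    ci <- c2_interval(inst$x, inst$y, alpha = alpha)
    expect_gte(ci$lower, 0)
    expect_lte(ci$upper, 1)
    expect_lte(ci$lower, ci$upper)
    tst <- c2_test(inst$x, inst$y, alpha = alpha)
    expect_equal(tst$reject, 0.5 < ci$lower || 0.5 > ci$upper)
    est <- mw_estimates(inst$x, inst$y)
    bk <- bk_interval(est$theta, est$m, alpha)
    expect_gte(bk$lower, 0)
    expect_lte(bk$upper, 1)
  }
})

test_that("intervals nest with the confidence level", {
  set.seed(53)
  for (i in 1:50) {
    inst <- random_instance(tie_pool = 1:6)
    est <- mw_estimates(inst$x, inst$y)
    wide <- c2_interval(inst$x, inst$y, alpha = 0.01)
    narrow <- c2_interval(inst$x, inst$y, alpha = 0.10)
    expect_lte(wide$lower, narrow$lower + 1e-12)
    expect_gte(wide$upper, narrow$upper - 1e-12)
    if (est$v_dl_sq > 0) {
      wb <- bm_interval(inst$x, inst$y, alpha = 0.01)
      nb <- bm_interval(inst$x, inst$y, alpha = 0.10)
      expect_lte(wb$lower, nb$lower + 1e-12)
      expect_gte(wb$upper, nb$upper - 1e-12)
    }
  }
})

test_that("separated samples delegate the Wilson interval to the bound form", {
  ci <- c2_interval(c(1, 2, 3, 4), c(6, 7, 8, 9))
  expect_equal(ci$method, "bk")
  expect_true(ci$delegated)
  expect_equal(ci$upper, 1)
  expect_equal(ci$lower, 4 / (4 + qchisq(0.95, 1)))
})

test_that("permutation interval: determinism and exhaustive quantile oracle", {
  d <- demo_metric()
  a <- permutation_interval(d$x, d$y, np = 400, seed = 3)
  b <- permutation_interval(d$x, d$y, np = 400, seed = 3)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
  x <- c(2, 5, 9); y <- c(1, 7, 8)
  ci <- permutation_interval(x, y, exhaustive = TRUE)
  pooled <- c(x, y)
  stats <- apply(combn(6, 3), 2, function(i)
    bm_stat_oracle(pooled[i], pooled[-i]))
  est <- mw_estimates(x, y)
  c1 <- quantile(stats, 0.975, names = FALSE, type = 1)
  c2q <- quantile(stats, 0.025, names = FALSE, type = 1)
  v <- sqrt(est$v_dl_sq / est$N)
  expect_equal(ci$lower, est$theta - c1 * v, tolerance = 1e-12)
  expect_equal(ci$upper, est$theta - c2q * v, tolerance = 1e-12)
})
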