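test_that("Satterthwaite df has the known closed forms", {
  expect_equal(satterthwaite_df(0.3, 0.3, 12, 12), 2 * (12 - 1))
  expect_equal(satterthwaite_df(0.3, 0, 9, 5), 9 - 1)
  expect_true(is.na(satterthwaite_df(0, 0, 5, 5)))
  expect_gt(satterthwaite_df(0.2, 0.7, 6, 11), 0)
})

test_that("Brunner-Munzel test reproduces the printed example", {
  d <- demo_metric()
  tst <- brunner_munzel_test(d$x, d$y)
  expect_equal(round(tst$p.value, 4), 0.0239)
  expect_true(tst$reject)
  z <- c(3, 1, 4, 1, 5)
  same <- brunner_munzel_test(z, z)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
})

test_that("Brunner-Munzel degenerate branch flags separated samples", {
  tst <- brunner_munzel_test(c(1, 2, 3), c(7, 8, 9))
  expect_true(tst$degenerate)
  expect_equal(unname(tst$statistic), Inf)
  expect_equal(tst$p.value, 0)
  const <- brunner_munzel_test(c(2, 2), c(2, 2))
  expect_true(const$degenerate)
  expect_equal(const$p.value, 1)
})

test_that("C-squared test reproduces the printed example and the chi2 link", {
  d <- demo_metric()
  tst <- c2_test(d$x, d$y)
  expect_equal(round(tst$p.value, 4), 0.0282)
  expect_false(tst$degenerate)
  # Remark-style identity: C2 == (theta - 1/2)^2 / sigma-tilde^2
  est <- mw_estimates(d$x, d$y)
  sig_tilde <- est$sigma_n_sq / (4 * est$theta * (1 - est$theta))
  expect_equal(unname(tst$statistic),
               (est$theta - 0.5)^2 / sig_tilde, tolerance = 1e-12)
  z <- c(2, 4, 4, 6)
  expect_equal(c2_test(z, z)$p.value, 1)
})

test_that("degenerate C-squared statistic equals m and sets the m thresholds", {
  tst <- c2_test(1:19, 21:39)
  expect_true(tst$degenerate)
  expect_equal(unname(tst$statistic), 19)
  # separated samples reject iff m >= 4 (alpha = .05) / m >= 7 (alpha = .01)
  rejects05 <- sapply(2:10, function(m)
    c2_test(1:m, (m + 1):(2 * m), alpha = 0.05)$reject)
  rejects01 <- sapply(2:10, function(m)
    c2_test(1:m, (m + 1):(2 * m), alpha = 0.01)$reject)
  expect_equal(min((2:10)[rejects05]), 4)
  expect_equal(min((2:10)[rejects01]), 7)
  # both samples a single shared constant: theta = 1/2, statistic 0
  const <- c2_test(c(5, 5, 5), c(5, 5))
  expect_true(const$degenerate)
  expect_equal(unname(const$statistic), 0)
  expect_equal(const$p.value, 1)
})

test_that("C-squared generalizes to H0: theta = theta0", {
  d <- demo_metric()
  expect_equal(c2_test(d$x, d$y, theta0 = 0.5)$p.value,
               c2_test(d$x, d$y)$p.value)
  # rejection of theta0 is equivalent to theta0 outside the Wilson interval
  set.seed(31)
  for (i in 1:50) {
    inst <- random_instance()
    est <- mw_estimates(inst$x, inst$y)
    if (est$separated || est$sigma_n_sq == 0) next
    ci <- c2_interval(inst$x, inst$y, alpha = 0.1)
    for (th0 in c(0.2, 0.45, 0.7)) {
      tst <- c2_test(inst$x, inst$y, alpha = 0.1, theta0 = th0)
      expect_equal(tst$reject, th0 < ci$lower || th0 > ci$upper)
    }
  }
})

test_that("test statistics are invariant under sample exchange", {
  set.seed(32)
  for (i in 1:30) {
    inst <- random_instance()
    expect_equal(abs(unname(brunner_munzel_test(inst$x, inst$y)$statistic)),
                 abs(unname(brunner_munzel_test(inst$y, inst$x)$statistic)),
                 tolerance = 1e-12)
    expect_equal(unname(c2_test(inst$x, inst$y)$statistic),
                 unname(c2_test(inst$y, inst$x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("permutation test is seeded-reproducible and handles extremes", {
  d <- demo_metric()
  a <- studentized_permutation_test(d$x, d$y, np = 500, seed = 99)
  b <- studentized_permutation_test(d$x, d$y, np = 500, seed = 99)
  expect_identical(a$p.value, b$p.value)
  expect_identical(a$conf.int, b$conf.int)
  # observed statistic 0 -> p capped at 1
  z <- c(1, 2, 3, 4)
  expect_equal(studentized_permutation_test(z, z, np = 200, seed = 1)$p.value, 1)
})

test_that("add-one rule reports 1/(np+1) when no permutation is as extreme", {
  s <- demo_ordinal()
  tst <- studentized_permutation_test(s$x, s$y, np = 999, seed = 5,
                                      p_rule = "add-one")
  u <- min(sum(tst$perm_stats <= unname(tst$statistic)),
           sum(tst$perm_stats >= unname(tst$statistic)))
  expect_equal(u, 0)  # observed statistic beyond every permuted one
  expect_equal(tst$p.value, 1 / (999 + 1))
})

test_that("exhaustive enumeration matches an independent brute-force oracle", {
  set.seed(41)
  for (rep in 1:5) {
    x <- sample(1:4, 3, replace = TRUE)
    y <- sample(1:4, 3, replace = TRUE)
    tst <- studentized_permutation_test(x, y, exhaustive = TRUE)
    pooled <- c(x, y)
    idx <- combn(6, 3)
    stats <- apply(idx, 2, function(i)
      bm_stat_oracle(pooled[i], pooled[-i]))
    t_obs <- bm_stat_oracle(x, y)
    p_oracle <- min(1, 2 * min(mean(stats <= t_obs), mean(stats >= t_obs)))
    expect_equal(ncol(idx), 20)
    expect_equal(tst$p.value, p_oracle)
  }
})
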