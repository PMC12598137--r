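test_that("samplers draw from the intended distributions", {
  set.seed(71)
  oc <- generate_sample("ordcat", list(shape1 = 1, shape2 = 1), 500)
  expect_true(all(oc %in% 1:5))
  expect_gt(length(unique(oc)), 1)
  nv <- generate_sample("normal", list(mean = 0, sd = 3), 1e5)
  expect_equal(var(nv), 9, tolerance = 0.1)
  l1 <- generate_sample("laplace", list(location = 0, scale = 1), 1e5)
  l3 <- generate_sample("laplace", list(location = 0, scale = 3), 1e5)
  expect_equal(var(l3) / var(l1), 9, tolerance = 0.5)
  expect_error(generate_sample("normal", list(mean = 0, sd = -1), 5), "positive")
  expect_error(generate_sample("gamma", list(shape = 1), 5), "unknown family")
})

test_that("true effect: closed forms, exact discrete sums, null pairs", {
  expect_equal(true_effect("beta", list(shape1 = 2, shape2 = 5),
                           "beta", list(shape1 = 2, shape2 = 5)), 0.5)
  expect_equal(true_effect("normal", list(mean = 0, sd = 1),
                           "normal", list(mean = 0, sd = 3)), 0.5)
  expect_equal(true_effect("exponential", list(rate = 3),
                           "exponential", list(rate = 1)), 0.75)
  # numeric integral agrees with the normal closed form
  mu <- 1.3
  expect_equal(true_effect("normal", list(mean = 0, sd = 1),
                           "normal", list(mean = mu, sd = 3)),
               pnorm(mu / sqrt(10)), tolerance = 1e-9)
  # discrete: matches a direct pairwise sum over category probabilities
  p1 <- diff(c(0, pbeta(c(.2, .4, .6, .8), 2, 5), 1))
  p2 <- diff(c(0, pbeta(c(.2, .4, .6, .8), 5, 5), 1))
  direct <- sum(outer(seq_len(5), seq_len(5), function(i, j)
    (i < j) + 0.5 * (i == j)) * outer(p1, p2))
  expect_equal(true_effect("ordcat", list(shape1 = 2, shape2 = 5),
                           "ordcat", list(shape1 = 5, shape2 = 5)),
               direct, tolerance = 1e-12)
  expect_equal(true_effect("poisson", list(lambda = 1),
                           "poisson", list(lambda = 1)), 0.5)
  # Monte-Carlo cross-check for a poisson pair
  pois_theta <- true_effect("poisson", list(lambda = 1),
                            "poisson", list(lambda = 3))
  set.seed(72)
  mc <- theta_oracle(rpois(3000, 1), rpois(3000, 3))
  expect_equal(pois_theta, mc, tolerance = 0.02)
})

test_that("effect-parameter solver inverts true_effect on a grid", {
  expect_equal(as.numeric(solve_effect_parameter("normal_eq", 0.5)), 0,
               tolerance = 1e-8)
  expect_equal(as.numeric(solve_effect_parameter("normal_eq", 0.8)),
               sqrt(2) * qnorm(0.8), tolerance = 1e-7)
  for (setting in c("normal_eq", "normal_het", "ordcat", "exponential")) {
    for (th in c(0.5, 0.6, 0.75, 0.88)) {
      p <- solve_effect_parameter(setting, th)
      sc <- attr(p, "scenario")
      expect_equal(true_effect(sc$f1$family, sc$f1$params,
                               sc$f2$family, sc$f2$params), th,
                   tolerance = 1e-7)
    }
  }
  expect_error(solve_effect_parameter("ordcat", 0.95), "not attainable")
})

test_that("simulation harnesses are reproducible and internally consistent", {
  sc <- mw_scenario("normal", list(mean = 0, sd = 1),
                    "normal", list(mean = 0, sd = 1), 15, 15)
  a <- simulate_type1(sc, tests = c("c2", "bm"), alpha = 0.05,
                      niter = 300, seed = 9)
  b <- simulate_type1(sc, tests = c("c2", "bm"), alpha = 0.05,
                      niter = 300, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$rate >= 0 & a$rate <= 1))
  expect_equal(a$mc_se, sqrt(a$rate * (1 - a$rate) / 300))
  zero <- simulate_type1(sc, tests = "c2", alpha = 0, niter = 100, seed = 2)
  expect_equal(zero$rate, 0)
})

test_that("power increases with the effect and is ~alpha at the null", {
  pw <- simulate_power("normal_eq", theta_grid = c(0.5, 0.75, 0.9),
                       n1 = 15, n2 = 15, tests = "c2", alpha = 0.05,
                       niter = 1500, seed = 10)
  expect_lt(abs(pw$rate[pw$theta == 0.5] - 0.05), 0.02)
  expect_gt(pw$rate[pw$theta == 0.9], pw$rate[pw$theta == 0.75])
  expect_gt(pw$rate[pw$theta == 0.75], pw$rate[pw$theta == 0.5])
})

test_that("coverage harness counts degenerates against the full denominator", {
  cv <- simulate_coverage(0.9, n1 = 5, n2 = 5, methods = c("c2", "bm"),
                          niter = 400, seed = 11)
  expect_true(all(cv$coverage >= 0 & cv$coverage <= 1))
  # small n at a large effect: separated replicates must occur and be counted
  expect_gt(sum(cv$n_degenerate[cv$method == "bm"]), 0)
})

test_that("scenario YAML config round-trips", {
  tmp <- tempfile(fileext = ".yml")
  writeLines(
    "- family1: normal\n  params1: {mean: 0, sd: 1}\n  family2: normal\n  params2: {mean: 0, sd: 3}\n  n1: 15\n  n2: 30\n  label: het-normal",
    tmp)
  sc <- read_scenarios(tmp)
  expect_length(sc, 1)
  expect_equal(sc[[1]]$label, "het-normal")
  expect_equal(sc[[1]]$f2$params$sd, 3)
  res <- simulate_type1(sc, tests = "c2", alpha = 0.05, niter = 100, seed = 1)
  expect_equal(nrow(res), 1)
})

test_that("tidy TSV output round-trips through write_sim_results", {
  sc <- mw_scenario("exponential", list(rate = 1),
                    "exponential", list(rate = 1), 10, 10)
  res <- simulate_type1(sc, tests = "c2", alpha = 0.05, niter = 100, seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_sim_results(res, tmp)
  back <- read.delim(tmp)
  expect_equal(back$rate, res$rate)
  expect_equal(names(back), names(res))
})
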