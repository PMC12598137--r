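#' Draw a sample from a study-design distribution family
#'
#' Families used by the Monte Carlo harnesses:
#' \describe{
#'   \item{\code{"normal"}}{\code{params = list(mean, sd)}.}
#'   \item{\code{"beta"}}{\code{params = list(shape1, shape2)}.}
#'   \item{\code{"ordcat"}}{5-point Likert scores: a Beta(\code{shape1},
#'     \code{shape2}) draw on \eqn{(0,1)} cut at \eqn{0.2, 0.4, 0.6, 0.8}
#'     into equal-width categories coded 1-5.}
#'   \item{\code{"poisson"}}{\code{params = list(lambda)}.}
#'   \item{\code{"exponential"}}{\code{params = list(rate)}; rate
#'     parameterization, so rate 1 has mean 1.}
#'   \item{\code{"laplace"}}{\code{params = list(location, scale)};
#'     location-scale with variance \eqn{2 b^2} for scale \eqn{b}.}
#' }
#'
#' @param family Family name, see Details.
#' @param params Named list of parameters.
#' @param n Sample size.
#' @return Numeric vector of length \code{n}.
#' @examples
#' table(generate_sample("ordcat", list(shape1 = 1, shape2 = 1), 100))
#' @export
generate_sample <- function(family, params, n) {
  check_family(family, params)
  switch(family,
    normal = stats::rnorm(n, params$mean, params$sd),
    beta = stats::rbeta(n, params$shape1, params$shape2),
    ordcat = discretize5(stats::rbeta(n, params$shape1, params$shape2)),
    poisson = stats::rpois(n, params$lambda),
    exponential = stats::rexp(n, params$rate),
    laplace = {
      u <- stats::runif(n) - 0.5
      params$location - params$scale * sign(u) * log(1 - 2 * abs(u))
    })
}

discretize5 <- function(u) findInterval(u, c(0.2, 0.4, 0.6, 0.8)) + 1

family_names <- c("normal", "beta", "ordcat", "poisson", "exponential", "laplace")

check_family <- function(family, params) {
  if (!family %in% family_names)
    stop(sprintf("unknown family '%s'", family))
  need <- switch(family,
    normal = c("mean", "sd"), beta = , ordcat = c("shape1", "shape2"),
    poisson = "lambda", exponential = "rate", laplace = c("location", "scale"))
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop(sprintf("family '%s' needs parameter(s): %s", family,
                 paste(miss, collapse = ", ")))
  pos <- setdiff(need, c("mean", "location"))
  bad <- vapply(pos, function(p) !is.finite(params[[p]]) || params[[p]] <= 0,
                logical(1))
  if (any(bad))
    stop(sprintf("parameter(s) %s must be positive", paste(pos[bad], collapse = ", ")))
  invisible(TRUE)
}

# distribution functions normalized for ties: list(cdf, pdf/pmf, discrete support)
family_funs <- function(family, params) {
  check_family(family, params)
  switch(family,
    normal = list(cdf = function(x) stats::pnorm(x, params$mean, params$sd),
                  pdf = function(x) stats::dnorm(x, params$mean, params$sd),
                  discrete = FALSE),
    beta = list(cdf = function(x) stats::pbeta(x, params$shape1, params$shape2),
                pdf = function(x) stats::dbeta(x, params$shape1, params$shape2),
                discrete = FALSE),
    exponential = list(cdf = function(x) stats::pexp(x, params$rate),
                       pdf = function(x) stats::dexp(x, params$rate),
                       discrete = FALSE),
    laplace = list(
      cdf = function(x) {
        z <- (x - params$location) / params$scale
        ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
      },
      pdf = function(x) exp(-abs(x - params$location) / params$scale) /
        (2 * params$scale),
      discrete = FALSE),
    poisson = {
      k <- 0:(stats::qpois(1 - 1e-14, params$lambda) + 10)
      list(support = k, pmf = stats::dpois(k, params$lambda), discrete = TRUE)
    },
    ordcat = {
      cuts <- c(0.2, 0.4, 0.6, 0.8)
      pr <- diff(c(0, stats::pbeta(cuts, params$shape1, params$shape2), 1))
      list(support = 1:5, pmf = pr, discrete = TRUE)
    })
}

#' True Mann-Whitney effect of a distribution pair
#'
#' Computes \eqn{\theta = \int F_1\, dF_2} (with \eqn{F} the tie-normalized
#' distribution function) exactly for discrete families, by closed form for
#' normal pairs (\eqn{\Phi((\mu_2-\mu_1)/\sqrt{\sigma_1^2+\sigma_2^2})}) and
#' exponential pairs (\eqn{\lambda_1/(\lambda_1+\lambda_2)}), and by
#' deterministic numerical integration otherwise.  Identical families with
#' identical parameters give exactly 1/2.
#'
#' @param family1,family2 Family names as in [generate_sample()].
#' @param params1,params2 Parameter lists.
#' @return The effect \eqn{\theta \in (0, 1)}.
#' @examples
#' true_effect("exponential", list(rate = 3), "exponential", list(rate = 1))  # 0.75
#' @export
true_effect <- function(family1, params1, family2, params2) {
  f1 <- family_funs(family1, params1)
  f2 <- family_funs(family2, params2)
  if (family1 == family2 &&
      isTRUE(all.equal(params1[order(names(params1))],
                       params2[order(names(params2))])))
    return(0.5)
  if (family1 == "normal" && family2 == "normal")
    return(stats::pnorm((params2$mean - params1$mean) /
                          sqrt(params1$sd^2 + params2$sd^2)))
  if (family1 == "exponential" && family2 == "exponential")
    return(params1$rate / (params1$rate + params2$rate))
  if (f1$discrete && f2$discrete) {
    supp <- sort(unique(c(f1$support, f2$support)))
    p1 <- pmf_on(f1, supp); p2 <- pmf_on(f2, supp)
    F1cum <- cumsum(p1)
    F1left <- c(0, F1cum[-length(F1cum)])
    return(sum(p2 * (F1left + p1 / 2)))
  }
  if (f1$discrete || f2$discrete)
    stop("mixed discrete/continuous pairs are not supported")
  stats::integrate(function(x) f1$cdf(x) * f2$pdf(x), -Inf, Inf,
                   rel.tol = 1e-10)$value
}

pmf_on <- function(f, supp) {
  p <- numeric(length(supp))
  p[match(f$support, supp)] <- f$pmf
  p
}

#' Solve a distribution parameter for a target effect
#'
#' For the power/coverage study settings, finds the free parameter of the
#' second (treatment) distribution so the pair attains a target Mann-Whitney
#' effect, by monotone root-finding on [true_effect()] (tolerance 1e-9):
#' \describe{
#'   \item{\code{"normal_eq"}}{\eqn{F_1 = N(0,1)}, \eqn{F_2 = N(\mu, 1)};
#'     solves \eqn{\mu}.}
#'   \item{\code{"normal_het"}}{\eqn{F_1 = N(0,1)}, \eqn{F_2 = N(\mu, 9)};
#'     solves \eqn{\mu}.}
#'   \item{\code{"ordcat"}}{5-point scores from \eqn{B(1,1)} vs
#'     \eqn{B(\alpha, 1)}; solves \eqn{\alpha}.  Attainable range is
#'     \eqn{(0.1, 0.9)} because the extreme categories retain half weight.}
#'   \item{\code{"exponential"}}{\eqn{F_1 = Exp(\lambda)}, \eqn{F_2 = Exp(1)};
#'     solves \eqn{\lambda}.}
#' }
#'
#' @param setting One of the names above.
#' @param target Target effect in \eqn{(0, 1)} (within the setting's
#'   attainable range).
#' @return The solved parameter value, with the full scenario pair attached as
#'   attribute \code{"scenario"} (a list \code{f1}, \code{f2}).
#' @examples
#' solve_effect_parameter("normal_eq", 0.8)  # sqrt(2) * qnorm(0.8)
#' @export
solve_effect_parameter <- function(setting = c("normal_eq", "normal_het",
                                               "ordcat", "exponential"),
                                   target) {
  setting <- match.arg(setting)
  if (target <= 0 || target >= 1) stop("target effect must lie in (0, 1)")
  build <- switch(setting,
    normal_eq = function(p) list(
      f1 = list(family = "normal", params = list(mean = 0, sd = 1)),
      f2 = list(family = "normal", params = list(mean = p, sd = 1))),
    normal_het = function(p) list(
      f1 = list(family = "normal", params = list(mean = 0, sd = 1)),
      f2 = list(family = "normal", params = list(mean = p, sd = 3))),
    ordcat = function(p) list(
      f1 = list(family = "ordcat", params = list(shape1 = 1, shape2 = 1)),
      f2 = list(family = "ordcat", params = list(shape1 = p, shape2 = 1))),
    exponential = function(p) list(
      f1 = list(family = "exponential", params = list(rate = p)),
      f2 = list(family = "exponential", params = list(rate = 1))))
  eff <- function(p) {
    sc <- build(p)
    true_effect(sc$f1$family, sc$f1$params, sc$f2$family, sc$f2$params) - target
  }
  interval <- switch(setting,
    normal_eq = , normal_het = c(-40, 40),
    ordcat = c(1e-6, 1e6),
    exponential = c(1e-9, 1e9))
  lo <- eff(interval[1]); hi <- eff(interval[2])
  if (sign(lo) == sign(hi))
    stop(sprintf("target effect %.3f is not attainable for setting '%s'",
                 target, setting))
  p <- stats::uniroot(eff, interval, tol = 1e-9)$root
  structure(p, scenario = build(p))
}

rep_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n, replace = TRUE)
}

mc_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Define a simulation scenario
#'
#' @param family1,params1,family2,params2 Distribution pair, as in
#'   [generate_sample()].
#' @param n1,n2 Sample sizes (each at least 2).
#' @param label Optional scenario label for result tables.
#' @return A list of class \code{"mw_scenario"}.
#' @export
mw_scenario <- function(family1, params1, family2, params2, n1, n2,
                        label = NULL) {
  check_family(family1, params1); check_family(family2, params2)
  if (n1 < 2 || n2 < 2) stop("sample sizes must be at least 2")
  structure(list(
    f1 = list(family = family1, params = params1),
    f2 = list(family = family2, params = params2),
    n1 = as.integer(n1), n2 = as.integer(n2),
    label = label %||% sprintf("%s-vs-%s_n%d-%d", family1, family2, n1, n2)
  ), class = "mw_scenario")
}

#' Read simulation scenarios from a YAML configuration file
#'
#' The file holds a top-level list; each element has keys \code{family1},
#' \code{params1}, \code{family2}, \code{params2}, \code{n1}, \code{n2} and
#' optionally \code{label}, mirroring [mw_scenario()].
#'
#' @param path Path to the YAML file.
#' @return A list of \code{"mw_scenario"} objects.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s)
    mw_scenario(s$family1, s$params1, s$family2, s$params2, s$n1, s$n2,
                label = s$label))
}

run_replicates <- function(scenario, tests, alpha, niter, seed, np, p_rule,
                           collect) {
  seeds <- rep_seeds(seed, niter)
  out <- vector("list", niter)
  for (i in seq_len(niter)) {
    set.seed(seeds[i])
    x <- generate_sample(scenario$f1$family, scenario$f1$params, scenario$n1)
    y <- generate_sample(scenario$f2$family, scenario$f2$params, scenario$n2)
    out[[i]] <- collect(x, y)
  }
  out
}

#' Monte Carlo type-I error study
#'
#' Simulates the rejection rate of the requested tests under null scenarios
#' (distribution pairs with true effect 1/2), at every level in \code{alpha}.
#' Degenerate replicates (separated samples and the like) are analyzed with
#' each test's degenerate branch, never dropped, and counted in the output.
#'
#' @param scenarios A list of [mw_scenario()] objects (or a single one).
#' @param tests Subset of \code{c("bm", "perm", "c2")}.
#' @param alpha Vector of two-sided levels.
#' @param niter Replications per scenario.
#' @param seed Master seed; per-replicate substream seeds are drawn from it,
#'   so results do not depend on evaluation order.
#' @param np Permutations per replicate when \code{"perm"} is requested.
#' @param p_rule Permutation p-value rule, see
#'   [studentized_permutation_test()].
#' @return A data.frame with one row per (scenario, test, alpha): columns
#'   \code{scenario}, \code{test}, \code{alpha}, \code{n1}, \code{n2},
#'   \code{rate}, \code{mc_se}, \code{n_degenerate}, \code{niter},
#'   \code{seed}.
#' @examples
#' sc <- mw_scenario("normal", list(mean = 0, sd = 1),
#'                   "normal", list(mean = 0, sd = 1), 15, 15)
#' simulate_type1(sc, tests = "c2", alpha = 0.05, niter = 200, seed = 1)
#' @export
simulate_type1 <- function(scenarios, tests = c("c2", "bm"),
                           alpha = c(0.05, 0.005), niter = 10000, seed = 1,
                           np = 2000, p_rule = "plain") {
  tests <- match.arg(tests, c("bm", "perm", "c2"), several.ok = TRUE)
  if (inherits(scenarios, "mw_scenario")) scenarios <- list(scenarios)
  do.call(rbind, lapply(seq_along(scenarios), function(s) {
    sc <- scenarios[[s]]
    theta0 <- true_effect(sc$f1$family, sc$f1$params, sc$f2$family, sc$f2$params)
    if (abs(theta0 - 0.5) > 1e-8)
      warning(sprintf("scenario '%s' is not a null scenario (theta = %.4f)",
                      sc$label, theta0))
    rejection_rates(sc, tests, alpha, niter, seed + s - 1, np, p_rule,
                    scenario_label = sc$label)
  }))
}

rejection_rates <- function(sc, tests, alpha, niter, seed, np, p_rule,
                            scenario_label) {
  reps <- run_replicates(sc, tests, alpha, niter, seed, np, p_rule,
    collect = function(x, y) {
      est <- mw_estimates(x, y)
      p <- c(bm = NA_real_, perm = NA_real_, c2 = NA_real_)
      deg <- c(bm = FALSE, perm = FALSE, c2 = FALSE)
      if ("bm" %in% tests) {
        t <- bm_test_from_estimates(est, alpha[1])
        p["bm"] <- t$p.value; deg["bm"] <- t$degenerate
      }
      if ("perm" %in% tests) {
        t <- studentized_permutation_test(x, y, alpha = alpha[1], np = np,
                                          seed = NULL, p_rule = p_rule)
        p["perm"] <- t$p.value; deg["perm"] <- t$degenerate
      }
      if ("c2" %in% tests) {
        t <- c2_test_from_estimates(est, alpha[1])
        p["c2"] <- t$p.value; deg["c2"] <- t$degenerate
      }
      list(p = p, deg = deg)
    })
  pmat <- t(vapply(reps, function(r) r$p, numeric(3)))
  degmat <- t(vapply(reps, function(r) r$deg, logical(3)))
  grid <- expand.grid(test = tests, alpha = alpha, stringsAsFactors = FALSE)
  data.frame(
    scenario = scenario_label,
    test = grid$test, alpha = grid$alpha,
    n1 = sc$n1, n2 = sc$n2,
    rate = mapply(function(tst, a) mean(pmat[, tst] < a), grid$test, grid$alpha),
    mc_se = mapply(function(tst, a) mc_se(mean(pmat[, tst] < a), niter),
                   grid$test, grid$alpha),
    n_degenerate = colSums(degmat)[grid$test],
    niter = niter, seed = seed,
    row.names = NULL
  )
}

#' Monte Carlo power study
#'
#' Simulates the power of the tests over a grid of target effects for one of
#' the power settings of [solve_effect_parameter()].  The treatment
#' distribution parameter is solved per grid point so the true effect equals
#' the target.
#'
#' @inheritParams simulate_type1
#' @param setting Power setting name, see [solve_effect_parameter()].
#' @param theta_grid Target effects (each in the setting's attainable range).
#' @param n1,n2 Sample sizes.
#' @return A data.frame as in [simulate_type1()] plus a \code{theta} column.
#' @export
simulate_power <- function(setting, theta_grid, n1 = 15, n2 = 15,
                           tests = c("c2", "bm"), alpha = 0.05, niter = 10000,
                           seed = 1, np = 2000, p_rule = "plain") {
  do.call(rbind, lapply(seq_along(theta_grid), function(j) {
    th <- theta_grid[j]
    par <- solve_effect_parameter(setting, th)
    sc0 <- attr(par, "scenario")
    sc <- mw_scenario(sc0$f1$family, sc0$f1$params, sc0$f2$family,
                      sc0$f2$params, n1, n2,
                      label = sprintf("%s_theta%.3f", setting, th))
    out <- rejection_rates(sc, tests, alpha, niter, seed + j - 1, np, p_rule,
                           scenario_label = sc$label)
    out$theta <- th
    out
  }))
}

#' Monte Carlo coverage study
#'
#' Simulates the empirical coverage of the confidence intervals over a grid of
#' true effects, for normal-shift alternatives (equal variances by default,
#' \code{sd2 = 3} for the heteroscedastic variant).  A replicate whose
#' interval is undefined (degenerate variance for the Brunner-Munzel and
#' permutation intervals) counts as non-coverage; the denominator is always
#' \code{niter}.  The chi-square interval is always defined (it falls back to
#' the variance-bound interval for separated samples).
#'
#' @inheritParams simulate_type1
#' @param theta_grid True effects in \eqn{(0, 1)}.
#' @param n1,n2 Sample sizes.
#' @param methods Subset of \code{c("bm", "perm", "c2")}.
#' @param level Confidence level.
#' @param sd2 Standard deviation of the second (shifted) normal sample.
#' @return A data.frame with columns \code{theta}, \code{method},
#'   \code{level}, \code{n1}, \code{n2}, \code{coverage}, \code{mc_se},
#'   \code{n_degenerate}, \code{niter}, \code{seed}.
#' @export
simulate_coverage <- function(theta_grid, n1 = 15, n2 = 15,
                              methods = c("c2", "bm"), level = 0.95,
                              niter = 10000, seed = 1, np = 2000, sd2 = 1) {
  methods <- match.arg(methods, c("bm", "perm", "c2"), several.ok = TRUE)
  alpha <- 1 - level
  setting <- if (sd2 == 1) "normal_eq" else "normal_het"
  do.call(rbind, lapply(seq_along(theta_grid), function(j) {
    th <- theta_grid[j]
    mu <- as.numeric(solve_effect_parameter(setting, th))
    sc <- mw_scenario("normal", list(mean = 0, sd = 1),
                      "normal", list(mean = mu, sd = sd2), n1, n2)
    reps <- run_replicates(sc, methods, alpha, niter, seed + j - 1, np, "plain",
      collect = function(x, y) {
        est <- mw_estimates(x, y)
        cov <- c(bm = NA, perm = NA, c2 = NA)
        deg <- c(bm = FALSE, perm = FALSE, c2 = FALSE)
        if ("bm" %in% methods) {
          if (est$v_dl_sq > 0) {
            ci <- bm_interval_from_estimates(est, alpha)
            cov["bm"] <- ci$lower <= th && th <= ci$upper
          } else { cov["bm"] <- FALSE; deg["bm"] <- TRUE }
        }
        if ("perm" %in% methods) {
          tst <- studentized_permutation_test(x, y, alpha = alpha, np = np)
          if (!anyNA(tst$conf.int)) {
            cov["perm"] <- tst$conf.int[1] <= th && th <= tst$conf.int[2]
          } else { cov["perm"] <- FALSE; deg["perm"] <- TRUE }
        }
        if ("c2" %in% methods) {
          ci <- c2_interval_from_estimates(est, alpha)
          cov["c2"] <- ci$lower <= th && th <= ci$upper
          deg["c2"] <- isTRUE(ci$delegated)
        }
        list(cov = cov, deg = deg)
      })
    covmat <- t(vapply(reps, function(r) as.logical(r$cov), logical(3)))
    degmat <- t(vapply(reps, function(r) r$deg, logical(3)))
    colnames(covmat) <- colnames(degmat) <- c("bm", "perm", "c2")
    data.frame(
      theta = th, method = methods, level = level, n1 = n1, n2 = n2,
      coverage = vapply(methods, function(m) mean(covmat[, m]), numeric(1)),
      mc_se = vapply(methods, function(m) mc_se(mean(covmat[, m]), niter),
                     numeric(1)),
      n_degenerate = colSums(degmat)[methods],
      niter = niter, seed = seed + j - 1,
      row.names = NULL)
  }))
}

#' Write simulation results as tidy TSV
#'
#' @param results A data.frame from one of the \code{simulate_*} harnesses.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sim_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
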