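#' Satterthwaite degrees of freedom
#'
#' Welch-Satterthwaite approximation of the degrees of freedom for the
#' Brunner-Munzel t-statistic:
#' \deqn{\hat f = \frac{(\hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2)^2}
#' {(\hat\sigma_1^2/n_1)^2/(n_1-1) + (\hat\sigma_2^2/n_2)^2/(n_2-1)}.}
#' For equal sizes and equal variance components this reduces to
#' \eqn{2(n-1)}; if one component vanishes it reduces to \eqn{n_i - 1}.
#'
#' @param sigma1_sq,sigma2_sq Per-sample variance components from
#'   [delong_variance()].
#' @param n1,n2 Sample sizes.
#' @return The estimated degrees of freedom, or \code{NA} with a warning-free
#'   degenerate marker when both components are zero (no t-quantile defined).
#' @export
satterthwaite_df <- function(sigma1_sq, sigma2_sq, n1, n2) {
  a <- sigma1_sq / n1
  b <- sigma2_sq / n2
  if (a + b == 0) return(NA_real_)
  (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
}

mw_test_result <- function(statistic, p_value, alpha, theta, method, reference,
                           df = NULL, degenerate = FALSE, conf_int = NULL,
                           data_name = NULL, extra = list()) {
  stat <- c(statistic = unname(statistic))
  names(stat) <- attr(statistic, "stat_name") %||% names(statistic) %||% "statistic"
  out <- c(list(
    statistic = stat,
    parameter = if (!is.null(df)) c(df = df),
    p.value = p_value,
    estimate = c("theta-hat" = theta),
    alternative = "two.sided",
    method = method,
    reference = reference,
    alpha = alpha,
    reject = isTRUE(p_value < alpha),
    degenerate = degenerate,
    conf.int = conf_int,
    data.name = data_name %||% "two samples"
  ), extra)
  class(out) <- c("mw_test", "htest")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brunner-Munzel test
#'
#' Tests \eqn{H_0: \theta = 1/2} with the studentized statistic
#' \eqn{T = \sqrt N (\hat\theta_N - 1/2)/\hat v_{DL}} referred to a central t
#' distribution with Satterthwaite-estimated degrees of freedom.  The
#' compatible confidence interval \eqn{\hat\theta_N \mp t_{\hat f, 1-\alpha/2}
#' \hat v_{DL}/\sqrt N} is attached; it is symmetric and not range-preserving.
#'
#' When \eqn{\hat v_{DL}^2 = 0} (completely separated or fully tied samples)
#' the statistic is undefined; the test then reports signed infinity with
#' p-value 0 (or statistic 0 with p-value 1 when \eqn{\hat\theta_N = 1/2}) and
#' sets the \code{degenerate} flag, so that simulation code can count these
#' replicates separately.  The confidence interval is \code{NA} in that case.
#'
#' @inheritParams rank_decompose
#' @param alpha Two-sided significance level.
#' @return An object of classes \code{"mw_test"} and \code{"htest"} with
#'   fields \code{statistic}, \code{parameter} (df), \code{p.value},
#'   \code{conf.int}, \code{estimate}, \code{reject}, \code{degenerate}.
#' @examples
#' brunner_munzel_test(rnorm(15), rnorm(15, 1))
#' @export
brunner_munzel_test <- function(x, y, alpha = 0.05) {
  est <- mw_estimates(x, y)
  dn <- paste(deparse1(substitute(x)), "vs", deparse1(substitute(y)))
  bm_test_from_estimates(est, alpha, data_name = dn)
}

bm_test_from_estimates <- function(est, alpha = 0.05, data_name = NULL) {
  theta <- est$theta; N <- est$N
  if (est$v_dl_sq == 0) {
    stat <- if (theta == 0.5) 0 else sign(theta - 0.5) * Inf
    p <- if (theta == 0.5) 1 else 0
    return(mw_test_result(stat, p, alpha, theta,
                          "Brunner-Munzel test (degenerate: v_DL^2 = 0)",
                          reference = "none (degenerate)", degenerate = TRUE,
                          conf_int = structure(c(NA_real_, NA_real_),
                                               conf.level = 1 - alpha),
                          data_name = data_name))
  }
  f <- satterthwaite_df(est$sigma1_sq, est$sigma2_sq, est$n1, est$n2)
  stat <- sqrt(N) * (theta - 0.5) / sqrt(est$v_dl_sq)
  p <- 2 * stats::pt(abs(stat), df = f, lower.tail = FALSE)
  ci <- bm_interval_from_estimates(est, alpha)
  mw_test_result(structure(stat, stat_name = "T"), p, alpha, theta,
                 "Brunner-Munzel test (Satterthwaite t-approximation)",
                 reference = sprintf("t distribution, %.4g df", f), df = f,
                 conf_int = structure(c(ci$lower, ci$upper), conf.level = 1 - alpha),
                 data_name = data_name)
}

#' Chi-square test for the Mann-Whitney effect (C-squared test)
#'
#' Tests \eqn{H_0: \theta = \theta_0} by approximating the variance of
#' \eqn{\hat\theta_N} through the estimated ratio of the true variance to its
#' Birnbaum-Klose upper bound \eqn{\theta(1-\theta)/m}: with
#' \eqn{\hat q = \hat\sigma_N^2/[\hat\theta(1-\hat\theta)]} the statistic
#' \deqn{C^2_{\theta_0} = \frac{(\hat\theta_N - \theta_0)^2}{\hat q\,
#' \theta_0 (1 - \theta_0)}}
#' is referred to a chi-square distribution with one degree of freedom; for
#' the default \eqn{\theta_0 = 1/2} it reduces to
#' \eqn{C^2 = 4 (\hat\theta_N - 1/2)^2 / \hat q}, equivalently
#' \eqn{(\hat\theta_N-1/2)^2/\tilde\sigma_N^2} with \eqn{\tilde\sigma_N^2 =
#' \hat\sigma_N^2/[4\hat\theta(1-\hat\theta)]}.  The null is rejected when the
#' statistic exceeds the \eqn{1-\alpha} chi-square quantile
#' \eqn{c_{1-\alpha} = z_{1-\alpha/2}^2}.
#'
#' For completely separated samples (\eqn{\hat\theta_N \in \{0,1\}}) or a
#' degenerate variance estimate (\eqn{\hat\sigma_N^2 = 0}) the ratio is
#' undefined and the variance is replaced by its sharp bound, giving
#' \eqn{C^2_{\sigma_{N,max}} = m(\hat\theta_N - \theta_0)^2 /
#' [\theta_0(1-\theta_0)]}, which for \eqn{\theta_0 = 1/2} is
#' \eqn{4m(\hat\theta_N - 1/2)^2} and equals \eqn{m} at
#' \eqn{\hat\theta_N \in \{0,1\}}; see [c2_degenerate_test()].
#'
#' The compatible Wilson-type confidence interval (range-preserving, from
#' [c2_interval()]) is attached.
#'
#' @inheritParams brunner_munzel_test
#' @param theta0 Null value of the effect, in \eqn{(0, 1)}; default 1/2.
#' @param mm1_factor Passed to [mw_estimates()].
#' @return An \code{"mw_test"} object; \code{degenerate} marks the
#'   variance-bound branch.
#' @examples
#' c2_test(rnorm(15), rnorm(15, 1))
#' @export
c2_test <- function(x, y, alpha = 0.05, theta0 = 0.5, mm1_factor = FALSE) {
  est <- mw_estimates(x, y, mm1_factor = mm1_factor)
  dn <- paste(deparse1(substitute(x)), "vs", deparse1(substitute(y)))
  c2_test_from_estimates(est, alpha, theta0, data_name = dn)
}

c2_test_from_estimates <- function(est, alpha = 0.05, theta0 = 0.5,
                                   data_name = NULL) {
  if (theta0 <= 0 || theta0 >= 1) stop("theta0 must lie strictly in (0, 1)")
  theta <- est$theta
  if (est$separated || est$sigma_n_sq == 0)
    return(c2_degenerate_from_estimates(est, alpha, theta0, data_name))
  stat <- (theta - theta0)^2 / (est$q_hat * theta0 * (1 - theta0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  ci <- c2_interval_from_estimates(est, alpha)
  mw_test_result(structure(stat, stat_name = "C^2"), p, alpha, theta,
                 "C-squared test (variance-ratio chi-square test)",
                 reference = "chi-square distribution, 1 df", df = 1,
                 conf_int = structure(c(ci$lower, ci$upper), conf.level = 1 - alpha),
                 data_name = data_name, extra = list(theta0 = theta0))
}

#' Degenerate-sample branch of the chi-square test
#'
#' When the unbiased variance estimate is zero -- in particular for completely
#' separated samples, where \eqn{\hat\theta_N \in \{0, 1\}} -- the variance is
#' replaced by the sharp Birnbaum-Klose bound \eqn{\theta(1-\theta)/m},
#' removing the need for variance estimation:
#' \eqn{C^2_{\sigma_{N,max}} = 4m(\hat\theta_N - 1/2)^2} (for
#' \eqn{\theta_0 = 1/2}), which equals \eqn{m} at the boundary.  Consequently
#' separated samples reject \eqn{H_0: \theta = 1/2} exactly when
#' \eqn{m \ge 4} at \eqn{\alpha = 0.05} and \eqn{m \ge 7} at
#' \eqn{\alpha = 0.01}.
#'
#' @inheritParams c2_test
#' @return An \code{"mw_test"} object with \code{degenerate = TRUE}.
#' @export
c2_degenerate_test <- function(x, y, alpha = 0.05, theta0 = 0.5) {
  est <- mw_estimates(x, y)
  c2_degenerate_from_estimates(est, alpha, theta0)
}

c2_degenerate_from_estimates <- function(est, alpha = 0.05, theta0 = 0.5,
                                         data_name = NULL) {
  theta <- est$theta; m <- est$m
  stat <- m * (theta - theta0)^2 / (theta0 * (1 - theta0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  ci <- bk_interval(theta, m, alpha)
  mw_test_result(structure(stat, stat_name = "C^2_max"), p, alpha, theta,
                 "C-squared test (variance-bound branch, sigma_N,max)",
                 reference = "chi-square distribution, 1 df", df = 1,
                 degenerate = TRUE,
                 conf_int = structure(c(ci$lower, ci$upper), conf.level = 1 - alpha),
                 data_name = data_name, extra = list(theta0 = theta0))
}

# BM statistic for a pooled vector split at n1; +/-Inf when the DeLong
# variance vanishes within a permutation (theta == 1/2 gives 0).
bm_stat_pooled <- function(pooled, n1) {
  N <- length(pooled)
  n2 <- N - n1
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  R <- rank(pooled, ties.method = "average")
  p1 <- R[i1] - rank(pooled[i1], ties.method = "average")
  p2 <- R[i2] - rank(pooled[i2], ties.method = "average")
  theta <- 2 * sum(p2) / (2 * n1 * n2)  # placement sum form, exact on its grid
  s1 <- sum((p1 - mean(p1))^2) / ((N - n1)^2 * (n1 - 1))
  s2 <- sum((p2 - mean(p2))^2) / ((N - n2)^2 * (n2 - 1))
  v <- N * (s1 / n1 + s2 / n2)
  if (v == 0) {
    if (theta == 0.5) 0 else sign(theta - 0.5) * Inf
  } else {
    sqrt(N) * (theta - 0.5) / sqrt(v)
  }
}

#' Studentized permutation test
#'
#' Permutes the pooled sample and recomputes the full Brunner-Munzel statistic
#' (ranks, placements and the DeLong variance re-derived) for each of
#' \code{np} random group reassignments.  The two-sided p-value is
#' \eqn{2 \min\{\hat P(T^* \le T), \hat P(T^* \ge T)\}} capped at 1
#' (\code{p_rule = "plain"}); with \code{p_rule = "add-one"} the identity
#' permutation is included, \eqn{p = (2U + 1)/(n_p + 1)} with \eqn{U} the
#' smaller tail count, so the smallest reportable p-value is
#' \eqn{1/(n_p + 1)} instead of 0.  Permuted datasets with a vanishing
#' variance estimate contribute signed infinity, keeping the permutation
#' distribution well defined.
#'
#' With \code{exhaustive = TRUE} all \eqn{\binom{N}{n_1}} distinct group
#' assignments are enumerated instead of sampling (intended for small
#' samples).
#'
#' @inheritParams brunner_munzel_test
#' @param np Number of random permutations.
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility; \code{NULL} leaves the RNG state alone).
#' @param p_rule \code{"plain"} or \code{"add-one"} (Phipson-Smyth-style
#'   correction).
#' @param exhaustive Enumerate the full permutation space instead of sampling.
#' @return An \code{"mw_test"} object; \code{perm_stats} holds the permuted
#'   statistics and \code{conf.int} the compatible permutation interval (see
#'   [permutation_interval()]).
#' @examples
#' studentized_permutation_test(rnorm(8), rnorm(8, 1), np = 500, seed = 1)
#' @export
studentized_permutation_test <- function(x, y, alpha = 0.05, np = 10000,
                                         seed = NULL,
                                         p_rule = c("plain", "add-one"),
                                         exhaustive = FALSE) {
  p_rule <- match.arg(p_rule)
  s <- check_two_samples(x, y)
  est <- mw_estimates(s$x, s$y)
  n1 <- est$n1; N <- est$N
  pooled <- c(s$x, s$y)
  t_obs <- bm_stat_pooled(pooled, n1)

  if (exhaustive) {
    idx <- utils::combn(N, n1)
    perm <- apply(idx, 2, function(i) bm_stat_pooled(c(pooled[i], pooled[-i]), n1))
    np <- length(perm)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(np), function(h) bm_stat_pooled(sample(pooled), n1),
                   numeric(1))
  }

  u_le <- sum(perm <= t_obs)
  u_ge <- sum(perm >= t_obs)
  p <- switch(p_rule,
    "plain"   = min(1, 2 * min(u_le, u_ge) / np),
    "add-one" = min(1, (2 * min(u_le, u_ge) + 1) / (np + 1)))

  ci <- if (est$v_dl_sq > 0) {
    c1 <- stats::quantile(perm, 1 - alpha / 2, names = FALSE, type = 1)
    c2 <- stats::quantile(perm, alpha / 2, names = FALSE, type = 1)
    v <- sqrt(est$v_dl_sq / N)
    structure(c(est$theta - c1 * v, est$theta - c2 * v), conf.level = 1 - alpha)
  } else structure(c(NA_real_, NA_real_), conf.level = 1 - alpha)

  mw_test_result(structure(t_obs, stat_name = "T"), p, alpha, est$theta,
                 sprintf("Studentized permutation test (%s)",
                         if (exhaustive) sprintf("exhaustive, %d assignments", np)
                         else sprintf("np = %d, %s rule", np, p_rule)),
                 reference = "empirical permutation distribution",
                 degenerate = est$v_dl_sq == 0,
                 conf_int = ci,
                 extra = list(perm_stats = perm, np = np, p_rule = p_rule,
                              seed = seed))
}
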