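#' Mann-Whitney effect estimate
#'
#' Estimates \eqn{\theta = P(X_1 < X_2) + \frac{1}{2} P(X_1 = X_2)}, the
#' probability that a random observation from the second sample exceeds one
#' from the first (ties counted half; also the area under the ROC curve).
#' The rank form \eqn{\hat\theta_N = (\bar R_{2\cdot} - (n_2+1)/2)/n_1}
#' equals the normalized pairwise count over all \eqn{n_1 n_2} pairs, so the
#' estimate is always a multiple of \eqn{1/(2 n_1 n_2)} in \eqn{[0, 1]}.
#'
#' @inheritParams rank_decompose
#' @return A list with \code{theta} (the estimate), \code{rank_mean_2} (mean
#'   overall rank of the second sample), and the sample sizes.
#' @examples
#' estimate_effect(c(1, 2, 3), c(1, 2, 3))$theta  # 0.5 by symmetry
#' @export
estimate_effect <- function(x, y) {
  rd <- rank_decompose(x, y)
  effect_from_ranks(rd)
}

effect_from_ranks <- function(rd) {
  # 2*sum(ranks) is integer-valued, so theta comes out exact on its
  # 1/(2 n1 n2) grid
  rsum2 <- sum(rd$overall[[2]])
  theta <- (2 * rsum2 - rd$n2 * (rd$n2 + 1)) / (2 * rd$n1 * rd$n2)
  list(theta = theta, rank_mean_2 = rsum2 / rd$n2, n1 = rd$n1, n2 = rd$n2)
}

#' All effect and variance estimates for two samples
#'
#' One pass over the rank decomposition yielding the effect estimate and every
#' variance quantity the tests consume: the DeLong plug-in components
#' \eqn{\hat\sigma_1^2, \hat\sigma_2^2, \hat v_{DL}^2}; the tie probability
#' \eqn{\hat\tau_N}; the unbiased rank-based variance \eqn{\hat\sigma_N^2}
#' (non-negative for all \eqn{n_i \ge 2} and bounded by
#' \eqn{\hat\theta(1-\hat\theta)/(m-1)}, the empirical Birnbaum-Klose
#' inequality); and the variance-ratio quantities
#' \eqn{\hat q = \hat\sigma_N^2/[\hat\theta(1-\hat\theta)]} and
#' \eqn{\hat r = \hat\theta(1-\hat\theta)/(m\,\hat\sigma_N^2)}.
#'
#' @inheritParams rank_decompose
#' @param mm1_factor Logical; if \code{TRUE}, scale \eqn{\hat q} by
#'   \eqn{m/(m-1)} (equivalently use the \eqn{(m-1)} form of the empirical
#'   bound in the ratio).  Default \code{FALSE}: the factor converges to 1 and
#'   is kept at 1.
#' @return An object of class \code{"mw_estimates"}: a list with fields
#'   \code{theta}, \code{sigma1_sq}, \code{sigma2_sq}, \code{v_dl_sq},
#'   \code{tau}, \code{sigma_n_sq}, \code{q_hat}, \code{r_hat}, sizes
#'   \code{n1}, \code{n2}, \code{N}, \code{m}, and the flags \code{separated}
#'   (\eqn{\hat\theta \in \{0, 1\}}) and \code{degenerate_variance}
#'   (\eqn{\hat\sigma_N^2 = 0} or \eqn{\hat v_{DL}^2 = 0}).  \code{q_hat} and
#'   \code{r_hat} are \code{NA} when their defining ratio is undefined; the
#'   caller must then route to the variance-bound branch.
#' @examples
#' est <- mw_estimates(rnorm(10), rnorm(10) + 1)
#' est$theta; est$v_dl_sq; est$sigma_n_sq
#' @export
mw_estimates <- function(x, y, mm1_factor = FALSE) {
  rd <- rank_decompose(x, y)
  estimates_from_ranks(rd, mm1_factor = mm1_factor)
}

estimates_from_ranks <- function(rd, mm1_factor = FALSE) {
  n1 <- rd$n1; n2 <- rd$n2; N <- rd$N; m <- rd$m
  theta <- effect_from_ranks(rd)$theta

  dl <- delong_variance(rd)
  tau <- tie_probability(rd)
  sn2 <- unbiased_variance(rd, theta = theta, tau = tau)

  tp <- theta * (1 - theta)
  separated <- theta == 0 || theta == 1
  q_hat <- if (separated) NA_real_ else (sn2 / tp) * if (mm1_factor) m / (m - 1) else 1
  r_hat <- if (separated || sn2 == 0) NA_real_ else tp / (m * sn2)

  structure(list(
    theta = theta, n1 = n1, n2 = n2, N = N, m = m,
    sigma1_sq = dl$sigma1_sq, sigma2_sq = dl$sigma2_sq, v_dl_sq = dl$v_dl_sq,
    tau = tau, sigma_n_sq = sn2, q_hat = q_hat, r_hat = r_hat,
    separated = separated,
    degenerate_variance = sn2 == 0 || dl$v_dl_sq == 0
  ), class = "mw_estimates")
}

#' DeLong variance estimator
#'
#' The plug-in estimator of the asymptotic variance of
#' \eqn{\sqrt N (\hat\theta_N - \theta)} used by the Brunner-Munzel test:
#' \eqn{\hat\sigma_i^2} is the empirical variance of the placements of sample
#' \eqn{i} scaled by \eqn{(N - n_i)^{-2}}, and
#' \eqn{\hat v_{DL}^2 = N(\hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2)}.
#' Positively biased for continuous (tie-free) data.
#'
#' @param rd A rank decomposition from [rank_decompose()].
#' @return List with \code{sigma1_sq}, \code{sigma2_sq}, \code{v_dl_sq}.
#' @export
delong_variance <- function(rd) {
  stopifnot(inherits(rd, "mw_ranks"))
  n <- c(rd$n1, rd$n2); N <- rd$N
  s2 <- vapply(1:2, function(i) {
    p <- rd$placement[[i]]
    sum((p - mean(p))^2) / ((N - n[i])^2 * (n[i] - 1))
  }, numeric(1))
  list(sigma1_sq = s2[1], sigma2_sq = s2[2],
       v_dl_sq = N * (s2[1] / n[1] + s2[2] / n[2]))
}

#' Estimated probability of cross-sample ties
#'
#' Estimates \eqn{\tau = P(X_1 = X_2)}, the tie mass in the overlap of the two
#' distributions, from the spread between maximum and minimum ranks:
#' \eqn{\hat\tau_N = \frac{1}{n_1}[(\bar R^+_{2\cdot} - \bar R^-_{2\cdot}) -
#' (\bar R^{(2)+}_{2\cdot} - \bar R^{(2)-}_{2\cdot})]}.  Equals the proportion
#' of tied pairs among all \eqn{n_1 n_2} cross-sample pairs; zero for data
#' without cross-sample ties.
#'
#' @inheritParams delong_variance
#' @return The estimate \eqn{\hat\tau_N \in [0, 1]}.
#' @export
tie_probability <- function(rd) {
  stopifnot(inherits(rd, "mw_ranks"))
  ((mean(rd$overall_max[[2]]) - mean(rd$overall_min[[2]])) -
     (mean(rd$internal_max[[2]]) - mean(rd$internal_min[[2]]))) / rd$n1
}

#' Unbiased rank-based variance estimator
#'
#' The unbiased estimator of \eqn{Var(\hat\theta_N)}:
#' \deqn{\hat\sigma_N^2 = \frac{1}{d_N}\Big[\sum_{i,k} (R^*_{ik} - \bar
#' R^*_{i\cdot})^2 - n_1 n_2 \big(\hat\theta(1-\hat\theta) -
#' \hat\tau_N/4\big)\Big],\quad d_N = n_1(n_1-1) n_2(n_2-1).}
#' Unbiased and non-negative for all \eqn{n_i \ge 2}, with the sharp empirical
#' Birnbaum-Klose bound \eqn{\hat\sigma_N^2 \le \hat\theta(1-\hat\theta)/(m-1)}.
#' Negative values smaller in magnitude than \code{1e-12} (floating-point
#' round-off in the placement sum) are clamped to zero.
#'
#' @inheritParams delong_variance
#' @param theta,tau Optional: the effect and tie-probability estimates; if
#'   missing they are computed from \code{rd}.
#' @return The estimate \eqn{\hat\sigma_N^2 \ge 0}.
#' @export
unbiased_variance <- function(rd, theta = NULL, tau = NULL) {
  stopifnot(inherits(rd, "mw_ranks"))
  if (is.null(theta)) theta <- effect_from_ranks(rd)$theta
  if (is.null(tau))   tau <- tie_probability(rd)
  n1 <- rd$n1; n2 <- rd$n2
  dN <- n1 * (n1 - 1) * n2 * (n2 - 1)
  ss <- sum(vapply(1:2, function(i) {
    p <- rd$placement[[i]]
    sum((p - mean(p))^2)
  }, numeric(1)))
  v <- (ss - n1 * n2 * (theta * (1 - theta) - tau / 4)) / dN
  if (v < 0) {
    if (v < -1e-12)
      stop("unbiased variance estimate substantially negative; this should be impossible")
    v <- 0
  }
  v
}

#' Variance-ratio quantities for the chi-square test
#'
#' The estimated ratio of the variance of \eqn{\hat\theta_N} to its
#' Birnbaum-Klose maximum \eqn{\theta(1-\theta)/m}:
#' \eqn{\hat r = \hat\theta(1-\hat\theta)/(m \hat\sigma_N^2)} and its
#' data-computable companion \eqn{\hat q = \hat\sigma_N^2 /
#' [\hat\theta(1-\hat\theta)]}.  The empirical Birnbaum-Klose bound implies
#' \eqn{\hat q \le 1/(m-1)}.
#'
#' @param theta Effect estimate in \eqn{(0, 1)}.
#' @param sigma_n_sq Unbiased variance estimate; must be positive for
#'   \code{r_hat}.
#' @param m Smaller of the two sample sizes.
#' @return List with \code{q_hat} and \code{r_hat} (\code{r_hat} is \code{NA}
#'   when \code{sigma_n_sq} is zero).
#' @export
variance_ratio <- function(theta, sigma_n_sq, m) {
  if (theta <= 0 || theta >= 1)
    stop("variance ratio undefined for theta in {0, 1}; use the variance-bound branch")
  tp <- theta * (1 - theta)
  list(q_hat = sigma_n_sq / tp,
       r_hat = if (sigma_n_sq > 0) tp / (m * sigma_n_sq) else NA_real_)
}

#' @export
print.mw_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("Mann-Whitney effect estimates (n1 = %d, n2 = %d)\n", x$n1, x$n2))
  cat(sprintf("  theta-hat      %.*f\n", digits, x$theta))
  cat(sprintf("  v_DL^2         %.*f\n", digits, x$v_dl_sq))
  cat(sprintf("  N * sigma_N^2  %.*f\n", digits, x$N * x$sigma_n_sq))
  cat(sprintf("  tau-hat        %.*f\n", digits, x$tau))
  if (x$separated) cat("  [samples completely separated]\n")
  invisible(x)
}
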