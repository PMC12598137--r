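mw_ci <- function(lower, upper, level, method, range_preserving, compatible_test,
                  delegated = FALSE) {
  structure(list(lower = lower, upper = upper, level = level, method = method,
                 range_preserving = range_preserving,
                 compatible_test = compatible_test, delegated = delegated),
            class = "mw_ci")
}

#' @export
print.mw_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%.0f%% confidence interval for theta (%s): [%.*f, %.*f]\n",
              100 * x$level, x$method, digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Brunner-Munzel confidence interval
#'
#' The interval obtained by inverting the Brunner-Munzel t-test:
#' \eqn{\hat\theta_N \mp t_{\hat f,1-\alpha/2}\, \hat v_{DL}/\sqrt N}.
#' Symmetric about \eqn{\hat\theta_N} and deliberately reported without
#' clipping: the bounds may fall outside \eqn{[0, 1]}, which is the method's
#' known defect for large effects.
#'
#' @inheritParams brunner_munzel_test
#' @return An \code{"mw_ci"} object with \code{range_preserving = FALSE}.
#' @examples
#' bm_interval(rnorm(15), rnorm(15, 2))
#' @export
bm_interval <- function(x, y, alpha = 0.05) {
  est <- mw_estimates(x, y)
  bm_interval_from_estimates(est, alpha)
}

bm_interval_from_estimates <- function(est, alpha = 0.05) {
  if (est$v_dl_sq == 0)
    stop("Brunner-Munzel interval undefined: DeLong variance estimate is zero",
         call. = FALSE)
  f <- satterthwaite_df(est$sigma1_sq, est$sigma2_sq, est$n1, est$n2)
  h <- stats::qt(1 - alpha / 2, df = f) * sqrt(est$v_dl_sq / est$N)
  mw_ci(est$theta - h, est$theta + h, 1 - alpha, "bm",
        range_preserving = FALSE, compatible_test = "bm")
}

#' Permutation confidence interval
#'
#' Inverts the studentized permutation test:
#' \eqn{[\hat\theta_N - c_1 \hat v_{DL}/\sqrt N,\; \hat\theta_N - c_2 \hat
#' v_{DL}/\sqrt N]} with \eqn{c_1, c_2} the empirical \eqn{1-\alpha/2} and
#' \eqn{\alpha/2} quantiles of the permuted statistics.
#'
#' @inheritParams studentized_permutation_test
#' @return An \code{"mw_ci"} object (not range-preserving).
#' @export
permutation_interval <- function(x, y, alpha = 0.05, np = 10000, seed = NULL,
                                 exhaustive = FALSE) {
  tst <- studentized_permutation_test(x, y, alpha = alpha, np = np, seed = seed,
                                      exhaustive = exhaustive)
  if (anyNA(tst$conf.int))
    stop("permutation interval undefined: DeLong variance estimate is zero",
         call. = FALSE)
  mw_ci(tst$conf.int[1], tst$conf.int[2], 1 - alpha, "perm",
        range_preserving = FALSE, compatible_test = "perm")
}

#' Wilson-type confidence interval compatible with the chi-square test
#'
#' Solves the quadratic inequality \eqn{(\hat\theta_N - \theta)^2 < \hat q\,
#' c_{1-\alpha}\, \theta(1-\theta)} for \eqn{\theta} (Wilson's construction
#' for binomial proportions applied to the Mann-Whitney effect), giving
#' \deqn{\theta_{L,U} = \frac{2\hat\theta_N + \hat q c \mp
#' \sqrt{\hat q^2 c^2 + 4 \hat q \hat\theta_N (1-\hat\theta_N) c}}
#' {2(1 + \hat q c)}, \qquad c = c_{1-\alpha}.}
#' The bounds always lie in \eqn{[0, 1]} (range-preserving), are asymmetric
#' about \eqn{\hat\theta_N} in general, and contain \eqn{1/2} exactly when
#' the chi-square test accepts \eqn{H_0: \theta = 1/2} at level \eqn{\alpha}.
#'
#' For separated samples or a zero variance estimate the interval delegates
#' transparently to the Birnbaum-Klose bound interval [bk_interval()]; the
#' returned method tag records the delegation.
#'
#' @inheritParams c2_test
#' @return An \code{"mw_ci"} object with \code{range_preserving = TRUE}.
#' @examples
#' c2_interval(rnorm(15), rnorm(15, 2))
#' @export
c2_interval <- function(x, y, alpha = 0.05, mm1_factor = FALSE) {
  est <- mw_estimates(x, y, mm1_factor = mm1_factor)
  c2_interval_from_estimates(est, alpha)
}

c2_interval_from_estimates <- function(est, alpha = 0.05) {
  if (est$separated || est$sigma_n_sq == 0) {
    ci <- bk_interval(est$theta, est$m, alpha)
    ci$delegated <- TRUE
    ci$compatible_test <- "c2"
    return(ci)
  }
  q <- est$q_hat
  cc <- stats::qchisq(1 - alpha, df = 1)
  qc <- q * cc
  th <- est$theta
  disc <- sqrt(qc^2 + 4 * qc * th * (1 - th))
  lo <- (2 * th + qc - disc) / (2 * (1 + qc))
  up <- (2 * th + qc + disc) / (2 * (1 + qc))
  mw_ci(lo, up, 1 - alpha, "c2", range_preserving = TRUE, compatible_test = "c2")
}

#' Birnbaum-Klose bound confidence interval
#'
#' Replaces the unknown variance of \eqn{\hat\theta_N} by its sharp upper
#' bound \eqn{\theta(1-\theta)/m} and solves
#' \eqn{(\hat\theta_N - \theta)^2 \le c_{1-\alpha}\, \theta(1-\theta)/m},
#' giving
#' \deqn{\theta_{L,U} = \frac{2m\hat\theta_N + c \mp
#' \sqrt{4m\hat\theta_N(1-\hat\theta_N) c + c^2}}{2(m + c)}.}
#' At the boundaries this turns one-sided: for \eqn{\hat\theta_N = 1} the
#' interval is \eqn{[m/(m+c),\, 1]}, for \eqn{\hat\theta_N = 0} it is
#' \eqn{[0,\, c/(m+c)]}.  Requires no variance estimation and is conservative
#' whenever the normal approximation of \eqn{\hat\theta_N} is adequate.
#'
#' @param theta Effect estimate in \eqn{[0, 1]}.
#' @param m Smaller of the two sample sizes (\eqn{\ge 2}).
#' @param alpha Two-sided significance level.
#' @return An \code{"mw_ci"} object with \code{range_preserving = TRUE}.
#' @examples
#' bk_interval(1, m = 4)   # one-sided [m/(m+c), 1]
#' @export
bk_interval <- function(theta, m, alpha = 0.05) {
  if (m < 2) stop("m must be at least 2")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  cc <- stats::qchisq(1 - alpha, df = 1)
  disc <- sqrt(4 * m * theta * (1 - theta) * cc + cc^2)
  lo <- (2 * m * theta + cc - disc) / (2 * (m + cc))
  up <- (2 * m * theta + cc + disc) / (2 * (m + cc))
  mw_ci(lo, up, 1 - alpha, "bk", range_preserving = TRUE, compatible_test = "c2")
}
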