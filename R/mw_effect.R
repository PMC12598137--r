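#' Two-sample analysis of the Mann-Whitney effect
#'
#' The package's central fitting function.  Estimates the Mann-Whitney effect
#' \eqn{\theta = P(X_1 < X_2) + \frac12 P(X_1 = X_2)} for two independent
#' samples and runs the requested tests of \eqn{H_0: \theta = 1/2} with their
#' compatible confidence intervals: the Brunner-Munzel t-approximation
#' (\code{"bm"}), the studentized permutation test (\code{"perm"}) and the
#' variance-ratio chi-square test (\code{"c2"}) with its range-preserving
#' Wilson-type interval.
#'
#' The effect is read as the tendency of the *second* sample toward larger
#' values: \eqn{\theta > 1/2} means observations from \code{y} tend to exceed
#' those from \code{x}.  For the formula interface the first factor level is
#' the first sample; \code{direction = "swap"} exchanges the roles (mapping
#' \eqn{\hat\theta \to 1 - \hat\theta}).
#'
#' @param x First sample (numeric), or a formula \code{value ~ group}.
#' @param ... Passed between methods.
#' @return An object of class \code{"mw_effect"}; see Details.  Supports
#'   \code{print()}, \code{summary()}, \code{coef()} (the effect estimate),
#'   \code{confint()} and \code{plot()}.
#' @details The returned object is a list with the observation vectors and
#'   labels, the full \code{estimates} (an \code{"mw_estimates"} object), one
#'   \code{"mw_test"} per requested method under \code{$tests}, the matching
#'   \code{"mw_ci"}s under \code{$intervals}, and the settings echo
#'   (\code{alpha}, \code{np}, \code{seed}, \code{p_rule}, \code{theta0},
#'   \code{direction}).
#' @examples
#' fit <- mw_effect(rnorm(20), rnorm(20, 1), tests = c("bm", "c2"))
#' summary(fit)
#' coef(fit)
#' confint(fit, method = "c2")
#' @export
mw_effect <- function(x, ...) UseMethod("mw_effect")

#' @rdname mw_effect
#' @param y Second sample (numeric).
#' @param tests Character subset of \code{c("bm", "perm", "c2")}.
#' @param alpha Two-sided significance level.
#' @param theta0 Null value for the chi-square test (default 1/2).
#' @param np,seed,p_rule Permutation-test settings, see
#'   [studentized_permutation_test()].
#' @param direction \code{"keep"} uses (\code{x}, \code{y}) as given,
#'   \code{"swap"} exchanges the samples.
#' @param labels Length-2 character vector naming the two samples.
#' @export
mw_effect.default <- function(x, y, tests = c("bm", "perm", "c2"),
                              alpha = 0.05, theta0 = 0.5, np = 10000,
                              seed = 20260928, p_rule = c("plain", "add-one"),
                              direction = c("keep", "swap"),
                              labels = c("sample 1", "sample 2"), ...) {
  tests <- match.arg(tests, c("bm", "perm", "c2"), several.ok = TRUE)
  p_rule <- match.arg(p_rule)
  direction <- match.arg(direction)
  if (direction == "swap") {
    tmp <- x; x <- y; y <- tmp
    labels <- rev(labels)
  }
  s <- check_two_samples(x, y)
  est <- mw_estimates(s$x, s$y)

  res_tests <- list()
  res_ci <- list()
  if ("bm" %in% tests) {
    res_tests$bm <- bm_test_from_estimates(est, alpha)
    res_ci$bm <- if (est$v_dl_sq > 0) bm_interval_from_estimates(est, alpha)
  }
  if ("perm" %in% tests) {
    tst <- studentized_permutation_test(s$x, s$y, alpha = alpha, np = np,
                                        seed = seed, p_rule = p_rule)
    res_tests$perm <- tst
    res_ci$perm <- if (!anyNA(tst$conf.int))
      mw_ci(tst$conf.int[1], tst$conf.int[2], 1 - alpha, "perm",
            range_preserving = FALSE, compatible_test = "perm")
  }
  if ("c2" %in% tests) {
    res_tests$c2 <- c2_test_from_estimates(est, alpha, theta0)
    res_ci$c2 <- c2_interval_from_estimates(est, alpha)
  }

  structure(list(
    x = s$x, y = s$y, labels = labels,
    estimates = est,
    tests = res_tests, intervals = res_ci,
    settings = list(alpha = alpha, theta0 = theta0, np = np, seed = seed,
                    p_rule = p_rule, direction = direction)
  ), class = "mw_effect")
}

#' @rdname mw_effect
#' @param data Data frame for the formula interface.
#' @export
mw_effect.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data = data)
  if (ncol(mf) != 2L) stop("formula must be of the form value ~ group")
  values <- mf[[1L]]
  g <- factor(mf[[2L]])
  if (nlevels(g) != 2L)
    stop(sprintf("grouping variable must have exactly 2 levels, found %d", nlevels(g)))
  lv <- levels(g)
  mw_effect.default(values[g == lv[1]], values[g == lv[2]], labels = lv, ...)
}

#' @export
print.mw_effect <- function(x, ...) {
  est <- x$estimates
  cat("Two-sample Mann-Whitney effect analysis\n")
  cat(sprintf("  %s (n1 = %d) vs %s (n2 = %d)\n",
              x$labels[1], est$n1, x$labels[2], est$n2))
  cat(sprintf("  theta-hat = %.4f  (tendency of '%s' toward larger values)\n",
              est$theta, x$labels[2]))
  for (nm in names(x$tests)) {
    tst <- x$tests[[nm]]
    ci <- x$intervals[[nm]]
    cat(sprintf("  %-4s p = %.4f%s%s\n", nm, tst$p.value,
                if (!is.null(ci)) sprintf("  CI[%.2f, %.2f]", ci$lower, ci$upper)
                else "  CI undefined",
                if (isTRUE(tst$degenerate)) "  [degenerate branch]" else ""))
  }
  invisible(x)
}

#' @export
summary.mw_effect <- function(object, ...) {
  structure(list(fit = object), class = "summary.mw_effect")
}

#' @export
print.summary.mw_effect <- function(x, ...) {
  fit <- x$fit
  est <- fit$estimates
  cat("Two-sample Mann-Whitney effect analysis\n\n")
  cat("Descriptive results\n")
  cat(sprintf("  Sample sizes        n1 = %d (%s), n2 = %d (%s)\n",
              est$n1, fit$labels[1], est$n2, fit$labels[2]))
  cat(sprintf("  Mann-Whitney effect theta-hat = %.3f\n", est$theta))
  cat(sprintf("  Cross-sample ties   tau-hat = %.3f\n", est$tau))
  cat("\nVariance estimates\n")
  cat(sprintf("  v_DL^2        = %.3f  (Brunner-Munzel / permutation test)\n",
              est$v_dl_sq))
  cat(sprintf("  N * sigma_N^2 = %.3f  (C-squared test)\n", est$N * est$sigma_n_sq))
  cat(sprintf("\nTests of H0: theta = %g (alpha = %g, two-sided)\n",
              fit$settings$theta0, fit$settings$alpha))
  for (nm in names(fit$tests)) {
    tst <- fit$tests[[nm]]
    ci <- fit$intervals[[nm]]
    cat(sprintf("  %-4s statistic = %8.4f  p = %.4f  %s  %s%s\n",
                nm, unname(tst$statistic), tst$p.value,
                if (tst$reject) "reject    " else "not reject",
                if (!is.null(ci)) sprintf("%.0f%% CI [%.2f, %.2f]",
                                          100 * ci$level, ci$lower, ci$upper)
                else "CI undefined",
                if (isTRUE(tst$degenerate)) "  [degenerate]" else ""))
  }
  invisible(x)
}

#' @export
coef.mw_effect <- function(object, ...) {
  c("theta" = object$estimates$theta)
}

#' Confidence intervals from a fitted analysis
#'
#' @param object An \code{"mw_effect"} fit.
#' @param parm Ignored (there is one parameter, \eqn{\theta}).
#' @param level Confidence level; intervals are recomputed at this level.
#' @param method Which interval: \code{"c2"}, \code{"bm"}, \code{"bk"} or
#'   \code{"perm"} (the latter reuses the stored permutation statistics).
#' @param ... Unused.
#' @return A 1-row matrix with columns \code{lower}, \code{upper}.
#' @export
confint.mw_effect <- function(object, parm = "theta", level = 0.95,
                              method = c("c2", "bm", "bk", "perm"), ...) {
  method <- match.arg(method)
  est <- object$estimates
  alpha <- 1 - level
  ci <- switch(method,
    c2 = c2_interval_from_estimates(est, alpha),
    bm = bm_interval_from_estimates(est, alpha),
    bk = bk_interval(est$theta, est$m, alpha),
    perm = {
      tst <- object$tests$perm
      if (is.null(tst)) stop("no permutation test stored in this fit")
      perm <- tst$perm_stats
      v <- sqrt(est$v_dl_sq / est$N)
      if (v == 0) stop("permutation interval undefined: DeLong variance is zero")
      c1 <- stats::quantile(perm, 1 - alpha / 2, names = FALSE, type = 1)
      c2q <- stats::quantile(perm, alpha / 2, names = FALSE, type = 1)
      mw_ci(est$theta - c1 * v, est$theta - c2q * v, level, "perm",
            FALSE, "perm")
    })
  out <- matrix(c(ci$lower, ci$upper), nrow = 1,
                dimnames = list("theta", c("lower", "upper")))
  attr(out, "method") <- ci$method
  out
}

#' @export
plot.mw_effect <- function(x, ...) {
  ints <- x$intervals[!vapply(x$intervals, is.null, logical(1))]
  if (!length(ints)) stop("no intervals to plot")
  k <- length(ints)
  lo <- vapply(ints, `[[`, numeric(1), "lower")
  up <- vapply(ints, `[[`, numeric(1), "upper")
  plot(NA, xlim = range(0, 1, lo, up), ylim = c(0.5, k + 0.5),
       xlab = expression(theta), ylab = "", yaxt = "n",
       main = "Compatible confidence intervals for the Mann-Whitney effect")
  graphics::axis(2, at = seq_len(k), labels = names(ints), las = 1)
  graphics::abline(v = c(0, 0.5, 1), lty = c(3, 2, 3), col = "grey50")
  graphics::segments(lo, seq_len(k), up, seq_len(k), lwd = 2)
  graphics::points(rep(x$estimates$theta, k), seq_len(k), pch = 19)
  invisible(x)
}

#' Serialize an analysis to a report list / JSON
#'
#' Produces a plain list mirroring the printed summary (data summary, effect
#' and variance estimates at full precision, per-method test results and
#' intervals, settings echo), suitable for lossless JSON export.  With the
#' same input and settings the JSON string is byte-identical across runs.
#'
#' @param fit An \code{"mw_effect"} object.
#' @param json If \code{TRUE} return a JSON string instead of a list.
#' @return A list, or a JSON character scalar if \code{json = TRUE}.
#' @export
mw_report <- function(fit, json = FALSE) {
  stopifnot(inherits(fit, "mw_effect"))
  est <- fit$estimates
  rep <- list(
    data = list(n1 = est$n1, n2 = est$n2, N = est$N,
                labels = fit$labels, tie_fraction = est$tau),
    estimates = list(theta = est$theta,
                     sigma1_sq = est$sigma1_sq, sigma2_sq = est$sigma2_sq,
                     v_dl_sq = est$v_dl_sq, tau = est$tau,
                     sigma_n_sq = est$sigma_n_sq,
                     N_sigma_n_sq = est$N * est$sigma_n_sq,
                     q_hat = est$q_hat, r_hat = est$r_hat,
                     separated = est$separated,
                     degenerate_variance = est$degenerate_variance),
    tests = lapply(fit$tests, function(t) list(
      statistic = unname(t$statistic), p_value = t$p.value,
      df = unname(t$parameter), reference = t$reference,
      reject = t$reject, degenerate = t$degenerate)),
    intervals = lapply(fit$intervals, function(ci) if (is.null(ci)) NULL else
      list(lower = ci$lower, upper = ci$upper, level = ci$level,
           method = ci$method, range_preserving = ci$range_preserving,
           compatible_test = ci$compatible_test)),
    settings = fit$settings
  )
  if (json) jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  else rep
}
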