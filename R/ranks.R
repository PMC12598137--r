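#' Midranks of a numeric vector
#'
#' Ranks with ties replaced by the average of the positions they occupy.
#' These are the ranks induced by the normalized distribution function
#' \eqn{F = (F^+ + F^-)/2}, which treats continuous and discrete data in a
#' unified way.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of midranks; sums to \code{length(x) * (length(x) + 1) / 2}.
#' @seealso [min_max_ranks()], [rank_decompose()]
#' @examples
#' midranks(c(1, 2, 2, 4))  # 1 2.5 2.5 4
#' @export
midranks <- function(x) {
  x <- check_obs(x)
  rank(x, ties.method = "average")
}

#' Minimum and maximum ranks
#'
#' The minimum rank of a value is one plus the number of observations strictly
#' below it; the maximum rank is the number of observations less than or equal
#' to it.  The midrank is their average, with equality of all three exactly for
#' untied values.
#'
#' @inheritParams midranks
#' @return A list with components \code{min} and \code{max}.
#' @export
min_max_ranks <- function(x) {
  x <- check_obs(x)
  list(min = rank(x, ties.method = "min"),
       max = rank(x, ties.method = "max"))
}

check_obs <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x) || !all(is.finite(x)))
    stop("observations must be a non-empty vector of finite values", call. = FALSE)
  x
}

check_two_samples <- function(x, y) {
  x <- check_obs(x)
  y <- check_obs(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations (variance estimation requires n_i >= 2)",
         call. = FALSE)
  list(x = x, y = y)
}

#' Rank decomposition of two samples
#'
#' Computes, for every observation, its overall mid/min/max rank among the
#' pooled \eqn{N = n_1 + n_2} values, its internal mid/min/max rank within its
#' own sample, and its placement \eqn{R^*_{ik} = R_{ik} - R^{(i)}_{ik}}: up to
#' tie-halving, the number of observations in the other sample that it
#' exceeds.  All rank-based estimators in the package are functions of this
#' decomposition.
#'
#' @param x,y Numeric vectors: the first and second sample.  Ties are exact
#'   equality of stored values; round ordinal inputs beforehand if needed.
#' @return An object of class \code{"mw_ranks"}: a list with per-sample
#'   components \code{overall}, \code{overall_min}, \code{overall_max},
#'   \code{internal}, \code{internal_min}, \code{internal_max},
#'   \code{placement} (each a list with elements \code{1} and \code{2}) and
#'   the sizes \code{n1}, \code{n2}, \code{N}, \code{m}.
#' @examples
#' rd <- rank_decompose(c(1, 2), c(3, 4))
#' rd$placement[[2]]  # 2 2: every first-sample value is exceeded
#' @export
rank_decompose <- function(x, y) {
  s <- check_two_samples(x, y)
  x <- s$x; y <- s$y
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  mid  <- rank(pooled, ties.method = "average")
  rmin <- rank(pooled, ties.method = "min")
  rmax <- rank(pooled, ties.method = "max")
  int_mid  <- list(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  int_min  <- list(rank(x, ties.method = "min"),     rank(y, ties.method = "min"))
  int_max  <- list(rank(x, ties.method = "max"),     rank(y, ties.method = "max"))
  structure(list(
    overall      = list(mid[i1], mid[i2]),
    overall_min  = list(rmin[i1], rmin[i2]),
    overall_max  = list(rmax[i1], rmax[i2]),
    internal     = int_mid,
    internal_min = int_min,
    internal_max = int_max,
    placement    = list(mid[i1] - int_mid[[1]], mid[i2] - int_mid[[2]]),
    n1 = n1, n2 = n2, N = N, m = min(n1, n2)
  ), class = "mw_ranks")
}

#' @export
print.mw_ranks <- function(x, ...) {
  cat(sprintf("Rank decomposition: n1 = %d, n2 = %d (N = %d)\n", x$n1, x$n2, x$N))
  cat(sprintf("  mean overall ranks: %.3f / %.3f\n",
              mean(x$overall[[1]]), mean(x$overall[[2]])))
  cat(sprintf("  mean placements:    %.3f / %.3f\n",
              mean(x$placement[[1]]), mean(x$placement[[2]])))
  invisible(x)
}
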