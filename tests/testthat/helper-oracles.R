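# Brute-force pairwise oracles, independent of the rank-based implementation.

theta_oracle <- function(x, y) {
  mean(outer(x, y, function(a, b) (a < b) + 0.5 * (a == b)))
}

tau_oracle <- function(x, y) {
  mean(outer(x, y, "=="))
}

# Plug-in (DeLong-style) variance oracle straight from the empirical
# distribution functions, without ranks.
delong_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  F1 <- function(t) mean((x < t) + 0.5 * (x == t))  # normalized edf
  F2 <- function(t) mean((y < t) + 0.5 * (y == t))
  v1 <- sapply(x, F2); v2 <- sapply(y, F1)
  s1 <- sum((v1 - mean(v1))^2) / (n1 - 1)
  s2 <- sum((v2 - mean(v2))^2) / (n2 - 1)
  N * (s1 / n1 + s2 / n2)
}

# Random small two-sample instance with a controllable tie intensity.
random_instance <- function(n1 = NULL, n2 = NULL, tie_pool = NULL) {
  n1 <- n1 %||% sample(2:8, 1)
  n2 <- n2 %||% sample(2:8, 1)
  if (is.null(tie_pool)) {
    tie_pool <- if (runif(1) < 0.5) 1:4 else NULL  # heavy ties half the time
  }
  draw <- function(n) if (is.null(tie_pool)) rnorm(n) else
    sample(tie_pool, n, replace = TRUE)
  list(x = draw(n1), y = draw(n2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Brunner-Munzel statistic used by the exhaustive-permutation
# oracle; deliberately re-derived from scratch.
bm_stat_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  th <- theta_oracle(x, y)
  F1 <- function(t) mean((x < t) + 0.5 * (x == t))
  F2 <- function(t) mean((y < t) + 0.5 * (y == t))
  v1 <- sapply(x, F2); v2 <- sapply(y, F1)
  s1 <- sum((v1 - mean(v1))^2) / (n1 - 1)
  s2 <- sum((v2 - mean(v2))^2) / (n2 - 1)
  v <- N * (s1 / n1 + s2 / n2)
  if (v == 0) { if (th == 0.5) 0 else sign(th - 0.5) * Inf }
  else sqrt(N) * (th - 0.5) / sqrt(v)
}

demo_metric <- function() demo_outcomes_data()
demo_ordinal <- function() shoulder_pain_data()
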