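---
title: "Rank-based inference for the Mann-Whitney effect: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based inference for the Mann-Whitney effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mweffect)
```

## The model and the estimand

We observe two independent samples $X_{ik} \sim F_i$, $k = 1, \dots, n_i$,
$i = 1, 2$, $N = n_1 + n_2$, with arbitrary distributions $F_i$ excluding
only one-point distributions. The estimand is the Mann-Whitney effect

$$\theta = \int F_1 \, dF_2 = P(X_1 < X_2) + \tfrac12 P(X_1 = X_2),$$

where $F = (F^+ + F^-)/2$ is the tie-normalized distribution function, so the
same formulas cover continuous, discrete and ordinal data. $\theta > 1/2$
means the second sample tends toward larger values; $\theta = 1/2$ is the
null of stochastic comparability. The hypothesis $H_0\colon \theta = 1/2$
with no further distributional assumptions is the nonparametric
Behrens-Fisher problem.

The estimator replaces $F_i$ by empirical distribution functions and reduces
to pooled-sample midranks:
$\hat\theta_N = (\bar R_{2\cdot} - (n_2+1)/2)/n_1$. `rank_decompose()`
computes the underlying decomposition: overall and within-sample mid-, min-
and max-ranks and the placements $R^*_{ik} = R_{ik} - R^{(i)}_{ik}$. Because
$2\sum_k R_{2k}$ is integer-valued, $\hat\theta_N$ is computed exactly on its
grid of multiples of $1/(2 n_1 n_2)$; ties are exact equality of stored
values (ordinal data arrive as exact integers; metric data should be rounded
by the caller if a coarser tie notion is wanted).

## Variance estimators

Two variance estimators of $\hat\theta_N$ drive the tests.

**DeLong plug-in** (`delong_variance()`): $\hat\sigma_i^2$ is the empirical
variance of the placements scaled by $(N - n_i)^{-2}$, and
$\hat v_{DL}^2 = N(\hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2)$ estimates the
variance of $\sqrt N(\hat\theta_N - \theta)$. It is consistent but biased —
positively so for continuous data, which the test suite checks by Monte
Carlo.

**Unbiased rank-based estimator** (`unbiased_variance()`):
$$\hat\sigma_N^2 = \frac{1}{d_N}\Big[\sum_{i,k}(R^*_{ik} - \bar
R^*_{i\cdot})^2 - n_1 n_2\big(\hat\theta(1-\hat\theta) -
\hat\tau_N/4\big)\Big], \qquad d_N = n_1(n_1-1)n_2(n_2-1),$$
with $\hat\tau_N$ the estimated cross-sample tie probability obtained from
the spread between max- and min-ranks (`tie_probability()`; it equals the
tied-pair proportion exactly). $\hat\sigma_N^2$ is unbiased, non-negative for
$n_i \ge 2$, and obeys the sharp *empirical Birnbaum-Klose bound*
$\hat\sigma_N^2 \le \hat\theta(1-\hat\theta)/(m-1)$, $m = \min(n_1, n_2)$.
Tiny negative values (below $10^{-12}$ in magnitude, pure round-off in the
placement sum) are clamped to zero; anything more negative is treated as an
internal error rather than silently truncated, since the estimator is
provably non-negative.

## The three tests and their intervals

**Brunner-Munzel** (`brunner_munzel_test()`):
$T = \sqrt N(\hat\theta_N - 1/2)/\hat v_{DL}$ referred to $t_{\hat f}$ with
Satterthwaite degrees of freedom
$\hat f = (\hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2)^2 / \sum_i
(\hat\sigma_i^2/n_i)^2/(n_i - 1)$
(`satterthwaite_df()`; reduces to $2(n-1)$ in the balanced equal-variance
case). The inverted interval $\hat\theta_N \mp t_{\hat f, 1-\alpha/2}\hat
v_{DL}/\sqrt N$ is reported *unclipped*: bounds outside $[0,1]$ are the
method's documented defect and hiding them would misrepresent it. A
display-level clip is deliberately not applied anywhere in the package.

**Studentized permutation** (`studentized_permutation_test()`): the pooled
vector is randomly re-split `np` times and the full statistic (ranks,
placements, DeLong variance) recomputed each time. The two-sided p-value is
$2\min\{\hat P(T^* \le T), \hat P(T^* \ge T)\}$ capped at 1; the `"add-one"`
rule includes the identity permutation, $p = (2U + 1)/(n_p + 1)$ with $U$ the
smaller tail count, so the smallest reportable p-value is $1/(n_p+1)$ rather
than 0. The plain rule is the default because it is the primary definition;
the add-one rule is the alternative recommended when exact-zero p-values must
be avoided. Permutations are simple seeded shuffles drawn with replacement
from the assignment space; an `exhaustive` flag enumerates all
$\binom{N}{n_1}$ assignments for small samples.

**C²-test** (`c2_test()`): instead of approximating the distribution of a
studentized statistic, the variance itself is approximated through the
estimated ratio of $\mathrm{Var}(\hat\theta_N)$ to its Birnbaum-Klose maximum
$\theta(1-\theta)/m$. With $\hat q = \hat\sigma_N^2/[\hat\theta(1 -
\hat\theta)]$ this gives $\mathrm{Var} \approx \hat q\,\theta(1-\theta)$ and
the pivot $(\hat\theta_N - \theta)^2 / [\hat q\,\theta(1-\theta)] \sim
\chi^2_1$; at $\theta_0 = 1/2$,
$$C^2 = 4(\hat\theta_N - 1/2)^2/\hat q
      = \frac{(\hat\theta_N - 1/2)^2}{\hat\sigma_N^2/[4\hat\theta(1-\hat\theta)]},$$
both forms computed from the same code path and asserted equal in the tests.
Solving the quadratic inequality in $\theta$ (Wilson's construction) yields
the compatible interval
$$\theta_{L,U} = \frac{2\hat\theta_N + \hat q c \mp \sqrt{\hat q^2 c^2 +
4\hat q \hat\theta_N(1-\hat\theta_N) c}}{2(1 + \hat q c)},
\qquad c = \chi^2_{1,1-\alpha},$$
whose bounds are always in $[0,1]$ and which contains $1/2$ iff the test
accepts. A general null $H_0\colon\theta = \theta_0$ is available through the
`theta0` argument, with the same pivot evaluated at $\theta_0$; rejecting
$\theta_0$ is equivalent to $\theta_0$ falling outside the Wilson interval.

**Degenerate samples.** Completely separated samples give
$\hat\theta_N \in \{0, 1\}$ and $\hat\sigma_N^2 = 0$, where ratio and
studentized statistics are undefined. Because the Birnbaum-Klose bound is
sharp, the variance is then *replaced by the bound*, giving
$C^2_{\sigma_{N,max}} = 4m(\hat\theta_N - 1/2)^2 = m$ at the boundary — so
separation alone rejects at $\alpha = 0.05$ iff $m \ge 4$ and at
$\alpha = 0.01$ iff $m \ge 7$ — and the interval becomes the one-sided bound
form $[m/(m+c), 1]$ (or $[0, c/(m+c)]$). The Wilson interval delegates to
this form automatically, recording the delegation in its method tag.

For the Brunner-Munzel and permutation statistics no published degenerate
rule is available in closed form, so the package adopts an explicit
convention: $\hat v_{DL}^2 = 0$ with $\hat\theta_N \ne 1/2$ yields a signed
infinite statistic with p-value 0, and $\hat\theta_N = 1/2$ yields p-value 1;
a `degenerate` flag is set in both cases, permuted replicates follow the same
rule, and the Monte Carlo harnesses count (never drop) such replicates. This
preserves monotonicity of evidence and keeps permutation distributions well
defined; its intervals remain undefined, which coverage simulations score as
non-coverage over the full denominator.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided level; tests are two-sided only |
| `theta0` | 0.5 | null effect of the C²-test (unitless, in (0,1)) |
| `np` | 10000 | permutations; p-value resolution is $1/n_p$ |
| `p_rule` | `"plain"` | permutation p-value rule (see above) |
| `mm1_factor` | `FALSE` | scales $\hat q$ by $m/(m-1)$, the variant implied by the empirical bound; kept off since the factor tends to 1 and brings no measurable size improvement |
| `direction` | `"keep"` | which group is the first sample; swapping maps $\hat\theta \to 1-\hat\theta$ |

The orientation matters for reporting: in the bundled shoulder-pain data the
treatment arm is the first sample, so $\theta$ is the probability that a
control patient's pain score exceeds a treated patient's, and values above
$1/2$ favour the treatment.

## The simulation harnesses

`generate_sample()` implements the study-design families: normal, beta,
5-point Likert scores (a Beta draw cut at $0.2, 0.4, 0.6, 0.8$ into
equal-width categories — a documented stand-in for the original
discretization, whose exact cut rule is not published in the body of the
source material), Poisson, exponential (rate parameterization) and Laplace
(variance $2b^2$, so $L(0,1)$ vs $L(0,3)$ has variance ratio 9). These
emulate the features that stress rank methods — skewness, heavy tails,
discreteness with massive ties, variance heteroscedasticity with positive or
negative pairing — but not real-data features such as measurement drift,
clustering or missingness; passing tests therefore demonstrate calibration
under the stated sampling models, not robustness to violations of
independence.

`true_effect()` computes $\theta$ exactly for discrete families, in closed
form for normal ($\Phi((\mu_2-\mu_1)/\sqrt{\sigma_1^2+\sigma_2^2})$) and
exponential ($\lambda_1/(\lambda_1+\lambda_2)$) pairs, and by deterministic
quadrature otherwise; `solve_effect_parameter()` inverts it by monotone
root-finding (tolerance $10^{-9}$) for the four power settings. Note the
Likert setting can only reach $\theta \in (0.1, 0.9)$ because the extreme
categories always retain half their tie mass.

Reproducibility uses one master seed from which a vector of per-replicate
seeds is drawn up front; each replicate re-seeds from its own entry, so
results are independent of evaluation order and a (scenario, seed) pair is
exactly reproducible. Rates are reported with the binomial Monte Carlo
standard error $\sqrt{\hat p(1-\hat p)/n_{iter}}$ and a count of degenerate
replicates.

## Problem sizes used in the shipped tests

The package's own test suite exercises the harnesses at desk scale, chosen as
the smallest sizes at which the checked bands are meaningful: size
calibration of the C²-test on four null normal designs ($n_i \in \{30, 60\}$,
equal and 9-fold variances) at $\alpha \in \{0.05, 0.005\}$ with $10^4$
replications against a $\pm 4$ Monte-Carlo-SE band; Wilson-interval coverage
at $n_1 = n_2 = 15$ over $\theta \in \{0.5, 0.6, 0.75, 0.85\}$ with $10^4$
replications against the nominal band at the null and Bradley's liberal
limit 0.925 elsewhere; and unbiasedness of $\hat\sigma_N^2$ against a
brute-force truth from $2\times10^5$ effect draws in three designs. Full-scale
studies ($10^5$ replications, all fourteen null settings, three sample-size
ladders) run through the same functions by passing larger `niter` and the
scenario lists.

## Known limitations

- The C²-test relies on asymptotic normality of $\hat\theta_N$; below about
  15 observations per arm the permutation test is the safer choice.
- All intervals, including the Wilson-type one, become liberal as $\theta$
  approaches the boundaries; interpret interval bounds cautiously for
  extreme effects in small samples.
- Highly skewed Likert data concentrated in few categories can degenerate
  the variance estimate and make the C²-test slightly liberal.
- One-sided tests, paired or $k$-sample designs, censored observations and
  effect comparisons between two biomarkers are out of scope.

## Session example

```{r example}
d <- demo_outcomes_data()
fit <- mw_effect(d$x, d$y, np = 2000, seed = 42, labels = d$labels)
summary(fit)
confint(fit, method = "c2")
```
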