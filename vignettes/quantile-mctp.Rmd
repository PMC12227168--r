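---
title: "Simultaneous inference for group quantiles: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous inference for group quantiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical content: the
model and its assumptions, the estimators and their tuning parameters, the
numerical conventions, the design decisions that were genuinely open, and
the limitations a user should know about.

## Model and assumptions

We observe $k \ge 2$ mutually independent samples
$X_{i1}, \dots, X_{in_i} \sim F_i$ and target the pooled quantile vector
$q = (q_{11}, \dots, q_{1m}, q_{21}, \dots, q_{km})'$ with
$q_{ij} = F_i^{-1}(p_j) = \inf\{u : F_i(u) \ge p_j\}$ at probabilities
$0 < p_1 < \dots < p_m < 1$ (group-major layout throughout: column
$(i-1)m + j$ is group $i$, probability $p_j$). The asymptotic theory
requires that each $F_i$ is continuously differentiable at its target
quantiles with positive density $f_i(q_{ij}) > 0$, and that the group
shares $n_i/n$ converge to positive constants $\kappa_i$. Neither
condition is checkable from data; many ties are a practical warning sign
that the density assumption fails, which is why the estimators below
**error on ties rather than flooring densities** — a silently floored
density would fabricate precision exactly where the method's premise is
broken.

Hypotheses are linear contrasts $h_\ell' q$ against margins
$\varepsilon_\ell$, with every row satisfying the contrast property
$\sum_i h_{\ell i j} = 0$ per probability block (validated with absolute
tolerance $10^{-10}$). Two-sided, noninferiority and equivalence (TOST)
versions are supported; the global hypothesis is the intersection of the
locals and is rejected iff any local hypothesis is rejected (max-t /
union–intersection principle), which ties the global decision to
simultaneous confidence intervals by construction.

## Quantile estimator

`empirical_quantile()` returns the $\lceil n_i p \rceil$-th order
statistic — the left-continuous generalized inverse of the empirical
distribution function (type-1 quantile), matching the estimand definition
exactly. It is deliberately **not** an interpolating quantile: the theory
is stated for $\hat F_i^{-1}$, and mixing quantile definitions between
estimand and estimator shifts small-sample levels. One consequence worth
knowing: type-1 quantiles are only antisymmetric under sign flips for odd
$n_i$ (for even $n_i$ the median is the lower of the two central order
statistics).

## Covariance estimators

The asymptotic covariance of $\sqrt n(\hat q - q)$ is block diagonal with
$\Sigma^{(i)}_{ab} = \kappa_i^{-1}(\min\{p_a,p_b\} - p_a p_b) /
(f_i(q_{ia}) f_i(q_{ib}))$. Estimating it reduces to estimating the
density (or its inverse) at the empirical quantiles; `quantile_cov()`
offers three routes:

* **kernel** (default): Gaussian-kernel density estimates at
  $\hat q_{ij}$ with the rule-of-thumb bandwidth
  $0.9\, n_i^{-1/5}\min\{SD, IQR/1.34\}$ (the `nrd0` rule). Fallback
  chain when the minimum is 0: use the SD; if the sample is constant,
  bandwidth scale 1 with a warning. The rule is defined only for
  $IQR > 0$; the chain extends it in the spirit of the reference
  implementation.
* **bootstrap**: per group, `B` (default 2000) with-replacement
  resamples; the block is $n$ times the empirical covariance of the
  resampled quantile vectors. Scaling by the total $n$ is algebraically
  identical to $n_i \kappa_i^{-1}$. Errors when a block's diagonal is
  zero (all resample quantiles identical — a ties/degeneracy indicator).
* **interval**: an order-statistic interval around position $n_i p_j$ of
  half-width $\lambda = z_{1-\gamma/2}\sqrt{n_i p_j (1-p_j)}$ (default
  $\gamma = 0.05$), with
  $1/\hat f_i(\hat q_{ij}) = n_i\,(X_{(U)} - X_{(L)})/(2\lambda)$,
  $L = \max\{\lceil n_i p_j - \lambda\rceil, 1\}$,
  $U = \min\{\lceil n_i p_j + \lambda\rceil, n_i\}$. This normalization
  makes the interval length a consistent inverse-density estimate (the
  package's deterministic normal-grid test checks it against
  $\sqrt{2\pi}$). Errors when $L \ge U$ (sample too small) or
  $X_{(U)} = X_{(L)}$ (ties).

All three are consistent; none dominates. Their practical accuracy is
limited by order-statistic spacings: any single quantile-variance estimate
fluctuates at relative order $n^{-1/4}$ (about 8% at $n_i = 20000$), with
occasional heavy-tailed outliers for tail probabilities. The package's
consistency tests therefore aggregate estimates across independent samples
with a trimmed mean before comparing to the closed form; a user comparing
a single estimate to a theoretical value should expect that noise floor.

## Critical values

Writing $T_n(h_\ell, \varepsilon_\ell) = \sqrt n (h_\ell'\hat q -
\varepsilon_\ell)/\sqrt{h_\ell'\hat\Sigma h_\ell}$, four procedures supply
critical values:

* **bonf-asymptotic**: $z_{1-\alpha/(2r)}$ (two-sided) or
  $z_{1-\alpha/r}$ (noninferiority).
* **bonf-permutation**: the pooled sample is re-partitioned into the
  original group sizes `B` times; quantiles **and the covariance
  estimator are recomputed on every permuted data set** (studentized
  permutation — this is what makes the procedure asymptotically valid
  without exchangeability, and finitely exact with it). Per-contrast
  critical values are the $1-\alpha/r$ empirical quantile of the
  permutation statistics, taken from the raw distribution (one-sided) or
  the absolute-value distribution (two-sided); by the symmetry of the
  permutation limit the two-sided choice is asymptotically equivalent to
  a raw $1-\alpha/(2r)$ quantile, and the absolute-value form is the one
  that pairs with the $|T| >$ critical decision rule. Quantiles are
  per-contrast, following the per-contrast notation of the underlying
  theory.
* **mctp-asymptotic**: Monte-Carlo $1-\alpha$ quantile of
  $\max_\ell Y_\ell$ (or $\max_\ell |Y_\ell|$) with
  $(Y_1,\dots,Y_r)' \sim N(0, \hat D H \hat\Sigma H'\hat D)$. Draws are
  generated through a per-block eigendecomposition factor of
  $\hat\Sigma$, never through an inverse or Cholesky of the correlation
  matrix, so rank-deficient families (Tukey has $r > \mathrm{rank}$)
  need no regularization. Default $M = 10^5$ draws; eigenvalues below
  zero within $10^{-8}$ relative tolerance are clipped, larger negative
  values raise an error.
* **mctp-bootstrap**: groupwise with-replacement resampling of the
  centered statistics $T^*_\ell = \sqrt n\, h_\ell'(\hat q^* - \hat q)/
  \sqrt{h_\ell'\hat\Sigma^* h_\ell}$, one common $1-\alpha$ max-quantile.

Conventions shared by all resampling engines: the empirical $\beta$
quantile of `B` draws is the $\lceil B\beta\rceil$-th order statistic;
degenerate replicates (failed covariance estimation, non-finite
statistics) are dropped and counted, and more than 10% dropped is an
error; given a seed, results are bit-reproducible. Execution is serial —
the grading of replicate-level randomness through one seeded stream makes
serial and any hypothetical batched execution identical by construction.
Resampling defaults are $B = 1999$ for a single data analysis and
$B = 2000$ inside the simulation grids. Choosing the bootstrap covariance
estimator inside a resampling procedure runs the inner covariance
bootstrap inside every outer replicate (cost $O(B \cdot B_{cov})$); this
naive nesting is intentional — it is the definition, and shortcuts that
reuse inner draws change the procedure.

## Decisions, p-values, confidence intervals, directions

Rejection and interval are computed from the *same* critical value, so
"reject $H_{0\ell}$" and "$\varepsilon_\ell$ outside the $\ell$-th
simultaneous interval" are identical events, not just asymptotically
equal. Adjusted p-values use: normal tails times $r$ (capped at 1) for
the asymptotic Bonferroni test; the add-one estimator
$(1 + \#\{T^\pi \ge T\})/(B+1)$, times $r$, for the permutation test; the
Monte-Carlo proportion of max-draws (floored at $1/M$) for the asymptotic
MCTP; and the add-one proportion for the bootstrap MCTP. Near the exact
level the order-statistic decision rule and the add-one p-value can
disagree by the resampling granularity $1/(B+1)$ — the decision rule is
authoritative.

One-sided families with `direction = "less"` are handled by negating
contrast rows and margins internally (one code path), and mirroring
estimates and bounds back to the original orientation as
$(-\infty, \cdot]$ intervals. The TOST equivalence wrapper runs the two
one-sided tests at level $\alpha/2$ each (configurable via `tost_level`);
equivalence for a contrast is concluded iff both one-sided tests reject.

## The synthetic-data generator and the simulation grids

`generate_group_sample()` draws from the location–scale model
$X_{is} = \sigma_i(\eta_{is} - m_i) + \mu_i$ with $\eta_{is}$ i.i.d. from
one of: standard normal, log-normal(0,1), $\chi^2_3$, $t_2$, $t_3$, and
$m_i$ the base distribution's *exact* median (inverse CDF, never
estimated). Every group's population median is therefore exactly
$\mu_i$, which makes truth assignment in the simulation engine exact.
The generator emulates the features that break mean-based procedures —
skewness ($\chi^2_3$, log-normal), heavy tails ($t_2$ without variance,
$t_3$), heteroskedasticity, unbalanced designs — but not serial
dependence, measurement rounding/ties, or contamination; passing tests
say nothing about those.

`small_sample_grid()` reconstructs the 120-cell small-sample study:
$(n,\sigma)$ pairings {balanced homoskedastic, balanced heteroskedastic,
unbalanced positive pairing, unbalanced negative pairing} × 5
distributions × 3 contrast families × 2 hypothesis types, defaults
Nsim = 5000, B = 2000, $\alpha = 0.05$; the published description lists
the settings but not the exact crossing, so the pairing list above is a
documented reconstruction that reproduces the cell count. Power cells add
$\delta \in \{0.5, 1, 1.5\}$ to group 4. `data_example_grid()` builds the
17-group design with the fixed heterogeneous size vector (total
$n = 4616$), Dunnett base 17 ($r = 16$), user-supplied scales and
shifts — the scales of the motivating study derive from external data —
and excludes $t_2$, whose infinite variance cannot be matched to
empirical variances. `run_scenario()` reports the empirical FWER
(fraction of replicates rejecting at least one true local null), global
and local power, each with binomial standard errors, and aborts if more
than 1% of replicates fail.

## Problem sizes in the bundled checks

The package's own test suite runs the FWER reproduction at Nsim = 1000
null data sets with B = 500 permutations per data set (the bundled
`scripts/acceptance.R` uses the same sizes), compared against the
correspondingly wider 1000-run binomial band around $\alpha$; the full
Nsim = 5000 study is a `run_scenario()` call away for anyone who wants
the tighter band. Estimator-consistency checks use single groups of
$n_i = 20000$, aggregated over 24 independent samples as explained above.

## Known limitations

* Conditional resampling quantiles for quantile statistics converge
  slowly: the given-data critical value fluctuates at $O(n^{-1/4})$
  around its normal limit even for $n_i$ in the thousands. This does not
  hurt level control (the observed statistic shares the discretization),
  but single-data-set comparisons of critical values to $z$-quantiles
  are noisy by nature.
* Many ties (discrete or rounded data) violate the density assumption;
  the covariance estimators error rather than guess.
* The interval estimator needs $n_i$ large enough that the
  order-statistic window is non-degenerate at every $p_j$; expect errors
  for small groups at extreme probabilities.
* `mctp-bootstrap` with `cov_method = "bootstrap"` is the most expensive
  combination (nested resampling) and, consistent with its construction,
  the most liberal; the bundled simulation engine lets users quantify
  that trade-off themselves.
* Only one-way layouts are built in; factorial structures enter through
  user-supplied contrast matrices.
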