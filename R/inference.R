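#' Simultaneous confidence intervals for quantile contrasts
#'
#' Two-sided: \eqn{h_\ell'\hat q \pm \sqrt{h_\ell'\hat\Sigma h_\ell}\,
#' \tilde q_\ell / \sqrt n}. Noninferiority (alternative
#' \eqn{h'q > \varepsilon}): \eqn{[h_\ell'\hat q - \sqrt{h_\ell'\hat\Sigma
#' h_\ell}\, q_\ell/\sqrt n,\ \infty)}; with `direction = "less"` the bound
#' is mirrored to \eqn{(-\infty,\ h_\ell'\hat q + \cdot]} on the original
#' contrast scale. The same critical values are used here and in the test
#' decisions, so rejection of \eqn{H_{0,\ell}} is equivalent to the margin
#' falling outside the interval.
#'
#' @param bundle a `stat_bundle` (computed on the internally oriented,
#'   i.e. `direction = "greater"`, family).
#' @param crit a `crit_values` object from the same run.
#' @param direction `"greater"` (default) or `"less"`; `"less"` mirrors the
#'   one-sided bound back to the original contrast orientation.
#' @return A data.frame with columns `estimate`, `lower`, `upper` on the
#'   original contrast scale.
#' @export
simultaneous_cis <- function(bundle, crit, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  est <- as.vector(bundle$family$H %*% bundle$quantiles$values)
  hw <- crit$values / (bundle$scale * sqrt(bundle$n))
  if (crit$alternative == "two_sided") {
    out <- data.frame(estimate = est, lower = est - hw, upper = est + hw)
  } else if (direction == "greater") {
    out <- data.frame(estimate = est, lower = est - hw, upper = Inf)
  } else {
    out <- data.frame(estimate = -est, lower = -Inf, upper = -est + hw)
  }
  rownames(out) <- bundle$family$row_labels
  out
}

#' Adjusted p-values for quantile contrast tests
#'
#' Per-contrast multiplicity-adjusted p-values, matched to the
#' critical-value procedure:
#' \describe{
#'   \item{bonf-asymptotic}{\eqn{\min\{1, r(1 - \Phi(T_\ell))\}} one-sided,
#'     \eqn{\min\{1, 2r(1 - \Phi(|T_\ell|))\}} two-sided.}
#'   \item{bonf-permutation}{Bonferroni-multiplied add-one permutation
#'     p-value \eqn{\min\{1, r (1 + \#\{T^\pi_{\ell,b} \ge T_\ell\})/(B+1)\}}
#'     (absolute values for two-sided).}
#'   \item{mctp-asymptotic}{Monte-Carlo proportion of max-draws at or above
#'     \eqn{T_\ell}, floored at \eqn{1/M}.}
#'   \item{mctp-bootstrap}{add-one proportion
#'     \eqn{(1 + \#\{\max_b \ge T_\ell\})/(B+1)} of bootstrap max-draws.}
#' }
#' Resampling p-values use the add-one estimator, so the smallest
#' attainable value is \eqn{1/(B+1)} (times r for the Bonferroni methods).
#'
#' @param bundle a `stat_bundle`.
#' @param crit a `crit_values` object with retained resampling draws where
#'   the method requires them.
#' @return Named numeric vector of length r.
#' @export
adjusted_p_values <- function(bundle, crit) {
  tn <- bundle$statistics
  r <- length(tn)
  two <- crit$alternative == "two_sided"
  tt <- if (two) abs(tn) else tn
  p <- switch(crit$method,
    "bonf-asymptotic" = {
      raw <- if (two) 2 * stats::pnorm(-tt) else stats::pnorm(-tt)
      pmin(1, r * raw)
    },
    "bonf-permutation" = {
      if (is.null(crit$draws)) stop("permutation draws not retained")
      drw <- if (two) abs(crit$draws) else crit$draws
      Beff <- ncol(drw)
      raw <- (1 + rowSums(drw >= tt)) / (Beff + 1)
      pmin(1, r * raw)
    },
    "mctp-asymptotic" = {
      if (is.null(crit$draws)) stop("Monte-Carlo max-draws not retained")
      pmax(vapply(tt, function(t0) mean(crit$draws >= t0), numeric(1)),
           1 / length(crit$draws))
    },
    "mctp-bootstrap" = {
      if (is.null(crit$draws)) stop("bootstrap max-draws not retained")
      Beff <- length(crit$draws)
      vapply(tt, function(t0) (1 + sum(crit$draws >= t0)) / (Beff + 1),
             numeric(1))
    },
    stop("unknown method: ", crit$method)
  )
  stats::setNames(p, names(tn))
}

.build_family <- function(contrast, k, base, margins) {
  if (inherits(contrast, "contrast_family")) {
    fam <- contrast
    if (!is.null(margins)) fam <- set_margins(fam, margins)
    return(fam)
  }
  if (is.matrix(contrast)) {
    return(contrast_custom(contrast, k = k,
                           margins = if (is.null(margins)) 0 else margins))
  }
  mg <- if (is.null(margins)) 0 else margins
  switch(match.arg(contrast, c("dunnett", "tukey", "grandmean")),
         dunnett = contrast_dunnett(k, base = base, margins = mg),
         tukey = contrast_tukey(k, margins = mg),
         grandmean = contrast_grandmean(k, margins = mg))
}

# shared core: runs one complete multiple test on the internally oriented
# family; returns lean components for both qmctp() and the simulation engine
.qmct_core <- function(gs, spec, family, alternative, method, cov_method,
                       alpha, B, M, B_cov, gamma) {
  cov <- quantile_cov(gs, spec, method = cov_method, B = B_cov, gamma = gamma)
  bundle <- studentized_contrasts(gs, spec, family, cov)
  crit <- switch(method,
    "bonf-asymptotic" = crit_bonf_asymptotic(alpha, nrow(family$H), alternative),
    "bonf-permutation" = crit_bonf_permutation(gs, spec, family, alpha = alpha,
                                               B = B, cov_method = cov_method,
                                               alternative = alternative,
                                               B_cov = B_cov, gamma = gamma),
    "mctp-asymptotic" = crit_mctp_asymptotic(family, cov, alpha = alpha,
                                             alternative = alternative, M = M),
    "mctp-bootstrap" = crit_mctp_bootstrap(gs, spec, family, alpha = alpha,
                                           B = B, cov_method = cov_method,
                                           alternative = alternative,
                                           B_cov = B_cov, gamma = gamma),
    stop("unknown method: ", method)
  )
  tt <- if (alternative == "two_sided") abs(bundle$statistics)
        else bundle$statistics
  reject <- as.vector(tt > crit$values)
  list(bundle = bundle, crit = crit, reject = reject, cov = cov)
}

#' Quantile-based multiple contrast test
#'
#' Runs a complete simultaneous test of \eqn{r} linear contrasts of group
#' quantiles: covariance estimation, studentized statistics, critical
#' values, per-contrast decisions, multiplicity-adjusted p-values,
#' simultaneous confidence intervals and the global decision. The global
#' null is rejected if and only if at least one local hypothesis is
#' rejected (union-intersection / max-t principle); rejection of a local
#' hypothesis is exactly equivalent to its margin lying outside the
#' reported simultaneous confidence interval.
#'
#' For `alternative = "noninferiority"` with `direction = "greater"` the
#' local alternative is \eqn{h_\ell' q > \varepsilon_\ell}; with
#' `direction = "less"` it is \eqn{h_\ell' q < \varepsilon_\ell}
#' (implemented by negating contrast rows and margins internally, with
#' estimates and confidence bounds reported back on the original scale as
#' \eqn{(-\infty, \cdot]} intervals).
#'
#' @param x observations: numeric vector (with `g`), list of numeric
#'   vectors, or a `grouped_sample`.
#' @param g grouping vector when `x` is numeric.
#' @param probs probabilities of interest (numeric vector or
#'   `quantile_spec`); default the median.
#' @param contrast `"dunnett"`, `"tukey"`, `"grandmean"`, a contrast
#'   matrix, or a `contrast_family` (e.g. from [contrast_med_iqr()]).
#' @param base base group for Dunnett-type contrasts.
#' @param margins margins \eqn{\varepsilon_\ell} (scalar or length r);
#'   `NULL` keeps the family's margins.
#' @param alternative `"two_sided"` or `"noninferiority"`.
#' @param direction for one-sided families: `"greater"` or `"less"`.
#' @param method `"bonf-permutation"` (default; recommended for small
#'   samples), `"bonf-asymptotic"`, `"mctp-asymptotic"` or
#'   `"mctp-bootstrap"`.
#' @param cov_method covariance estimator: `"kernel"`, `"bootstrap"` or
#'   `"interval"`.
#' @param alpha global significance level.
#' @param B resampling iterations for permutation/bootstrap critical
#'   values.
#' @param M Monte-Carlo draws for the asymptotic MCTP critical value.
#' @param B_cov bootstrap replicates for the bootstrap covariance
#'   estimator.
#' @param gamma interval level for the interval covariance estimator.
#' @param seed seed set once at the start of the run; mandatory for
#'   reproducible resampling output.
#' @return An object of class `qmctp`: list with `table` (per-contrast
#'   data.frame: estimate, margin, statistic, crit, p_adj, lower, upper,
#'   reject), `global_rejected`, and metadata (`method`, `cov_method`,
#'   `alternative`, `direction`, `alpha`, `B`, `M`, `seed`, `sizes`,
#'   plus the underlying `bundle` and `crit`).
#' @examples
#' set.seed(1)
#' x <- list(rnorm(25), rnorm(25, 1), rnorm(25))
#' qmctp(x, contrast = "dunnett", method = "bonf-asymptotic")
#' @export
qmctp <- function(x, g = NULL, probs = 0.5, contrast = "dunnett", base = 1L,
                  margins = NULL,
                  alternative = c("two_sided", "noninferiority"),
                  direction = c("greater", "less"),
                  method = c("bonf-permutation", "bonf-asymptotic",
                             "mctp-asymptotic", "mctp-bootstrap"),
                  cov_method = c("kernel", "bootstrap", "interval"),
                  alpha = 0.05, B = 1999L, M = 1e5, B_cov = 2000L,
                  gamma = 0.05, seed = NULL) {
  alternative <- match.arg(alternative)
  direction <- match.arg(direction)
  method <- match.arg(method)
  cov_method <- match.arg(cov_method)
  gs <- if (inherits(x, "grouped_sample")) x else grouped_sample(x, g)
  if (gs$k < 2L) stop("at least two groups are required for inference")
  spec <- if (inherits(probs, "quantile_spec")) probs else quantile_spec(probs)
  family <- .build_family(contrast, gs$k, base, margins)
  vr <- validate_contrasts(family, gs$k, spec = spec)
  if (!vr$ok) stop(vr$message)
  if (!is.null(seed)) set.seed(seed)

  flip <- alternative == "noninferiority" && direction == "less"
  fam_int <- if (flip) {
    f <- family; f$H <- -f$H; f$margins <- -f$margins; f
  } else family

  core <- .qmct_core(gs, spec, fam_int, alternative, method, cov_method,
                     alpha, B, M, B_cov, gamma)
  cis <- simultaneous_cis(core$bundle, core$crit,
                          direction = if (flip) "less" else "greater")
  pvals <- adjusted_p_values(core$bundle, core$crit)
  global <- any(core$reject)
  stopifnot(identical(global, any(core$reject)))  # global = OR of locals

  tab <- data.frame(
    contrast = family$row_labels,
    estimate = cis$estimate,
    margin = family$margins,
    statistic = as.vector(core$bundle$statistics),
    crit = as.vector(core$crit$values),
    p_adj = as.vector(pvals),
    lower = cis$lower,
    upper = cis$upper,
    reject = core$reject,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, global_rejected = global, method = method,
                 cov_method = cov_method, alternative = alternative,
                 direction = direction, alpha = alpha,
                 B = if (method %in% c("bonf-permutation", "mctp-bootstrap")) B else NULL,
                 M = if (method == "mctp-asymptotic") M else NULL,
                 seed = seed, sizes = gs$sizes, labels = gs$labels,
                 probs = spec$p, family = family,
                 bundle = core$bundle, crit = core$crit),
            class = "qmctp")
}

#' @export
print.qmctp <- function(x, digits = 4, ...) {
  cat("Quantile-based multiple contrast test\n")
  cat(sprintf("  method: %s | covariance: %s | alternative: %s%s | alpha = %g\n",
              x$method, x$cov_method, x$alternative,
              if (x$alternative == "noninferiority")
                paste0(" (", x$direction, ")") else "",
              x$alpha))
  cat(sprintf("  k = %d groups, n = %s\n", length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Global hypothesis %s at level %g.\n",
              if (x$global_rejected) "REJECTED" else "not rejected", x$alpha))
  invisible(x)
}

#' Equivalence test for quantile contrasts (TOST)
#'
#' Tests \eqn{H_{0,\ell}^E: |h_\ell' q| \ge \delta_\ell} against
#' \eqn{|h_\ell' q| < \delta_\ell} by two one-sided noninferiority-style
#' tests, each run at level `alpha / 2`: one ruling out
#' \eqn{h'q \le -\delta_\ell}, one ruling out \eqn{h'q \ge \delta_\ell}.
#' Equivalence is concluded for a contrast iff both one-sided tests reject.
#'
#' @inheritParams qmctp
#' @param delta positive equivalence half-widths \eqn{\delta_\ell} (scalar
#'   or length r).
#' @param tost_level level of each one-sided test; defaults to
#'   `alpha / 2`.
#' @return An object of class `qmctp_tost`: list with `table` (per-contrast
#'   estimate, delta, decisions of both one-sided runs, equivalence
#'   decision), `global_equivalent` (all contrasts equivalent), and the two
#'   underlying `qmctp` runs (`lower_run`, `upper_run`).
#' @export
qmctp_equivalence <- function(x, g = NULL, probs = 0.5, contrast = "dunnett",
                              base = 1L, delta, alpha = 0.05,
                              tost_level = alpha / 2,
                              method = c("bonf-permutation", "bonf-asymptotic",
                                         "mctp-asymptotic", "mctp-bootstrap"),
                              cov_method = c("kernel", "bootstrap", "interval"),
                              B = 1999L, M = 1e5, B_cov = 2000L, gamma = 0.05,
                              seed = NULL) {
  method <- match.arg(method)
  cov_method <- match.arg(cov_method)
  gs <- if (inherits(x, "grouped_sample")) x else grouped_sample(x, g)
  spec <- if (inherits(probs, "quantile_spec")) probs else quantile_spec(probs)
  family <- .build_family(contrast, gs$k, base, NULL)
  r <- nrow(family$H)
  if (length(delta) == 1L) delta <- rep(delta, r)
  if (length(delta) != r) stop("'delta' must have length 1 or r")
  if (any(delta <= 0)) stop("all equivalence half-widths must be positive")
  if (!is.null(seed)) set.seed(seed)

  # H1: h'q > -delta at level tost_level
  lower_run <- qmctp(gs, probs = spec, contrast = family, margins = -delta,
                     alternative = "noninferiority", direction = "greater",
                     method = method, cov_method = cov_method,
                     alpha = tost_level, B = B, M = M, B_cov = B_cov,
                     gamma = gamma)
  # H1: h'q < +delta at level tost_level
  upper_run <- qmctp(gs, probs = spec, contrast = family, margins = delta,
                     alternative = "noninferiority", direction = "less",
                     method = method, cov_method = cov_method,
                     alpha = tost_level, B = B, M = M, B_cov = B_cov,
                     gamma = gamma)
  equivalent <- lower_run$table$reject & upper_run$table$reject
  tab <- data.frame(
    contrast = family$row_labels,
    estimate = lower_run$table$estimate,
    delta = delta,
    reject_lower = lower_run$table$reject,
    reject_upper = upper_run$table$reject,
    equivalent = equivalent,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, global_equivalent = all(equivalent),
                 alpha = alpha, tost_level = tost_level, method = method,
                 cov_method = cov_method, seed = seed,
                 lower_run = lower_run, upper_run = upper_run),
            class = "qmctp_tost")
}

#' @export
print.qmctp_tost <- function(x, digits = 4, ...) {
  cat("Quantile contrast equivalence test (TOST)\n")
  cat(sprintf("  method: %s | covariance: %s | one-sided level = %g\n",
              x$method, x$cov_method, x$tost_level))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Equivalence for all contrasts: %s\n",
              if (x$global_equivalent) "yes" else "no"))
  invisible(x)
}
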