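#' Grouped sample container
#'
#' Holds k mutually independent groups of real-valued observations.
#'
#' @param x either a list of numeric vectors (one per group) or a numeric
#'   vector of observations.
#' @param g grouping vector (factor-like) when `x` is a numeric vector;
#'   group order follows first appearance unless `g` is already a factor.
#' @param labels optional group labels when `x` is a list.
#' @return An object of class `grouped_sample` with elements `groups`
#'   (list of numeric vectors), `sizes`, `n`, `k`, `labels`.
#' @examples
#' grouped_sample(list(rnorm(10), rnorm(12)))
#' grouped_sample(c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
#' @export
grouped_sample <- function(x, g = NULL, labels = NULL) {
  if (is.list(x)) {
    groups <- lapply(x, as.numeric)
    if (is.null(labels)) {
      labels <- if (!is.null(names(x))) names(x) else paste0("g", seq_along(x))
    }
  } else {
    if (is.null(g)) stop("'g' is required when 'x' is not a list")
    if (length(g) != length(x)) stop("'x' and 'g' must have equal length")
    f <- if (is.factor(g)) g else factor(g, levels = unique(as.character(g)))
    groups <- split(as.numeric(x), f)
    labels <- levels(f)
  }
  if (length(groups) < 1L) stop("at least one group required")
  if (any(vapply(groups, length, 1L) < 1L)) stop("every group needs >= 1 observation")
  if (!all(vapply(groups, function(v) all(is.finite(v)), logical(1)))) {
    stop("all observations must be finite")
  }
  sizes <- vapply(groups, length, 1L)
  structure(list(groups = unname(groups), sizes = unname(sizes),
                 n = sum(sizes), k = length(groups),
                 labels = as.character(labels)),
            class = "grouped_sample")
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat(sprintf("Grouped sample: k = %d groups, n = %d total\n", x$k, x$n))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Empirical quantile (left-continuous inverse)
#'
#' Returns the \eqn{\lceil n p \rceil}-th order statistic, i.e. the
#' generalized inverse \eqn{\hat F^{-1}(p) = \inf\{u : \hat F(u) \ge p\}} of
#' the empirical distribution function (type-1 quantile). This is
#' deliberately not an interpolating quantile: it matches the estimand
#' \eqn{q = F^{-1}(p)} definition exactly.
#'
#' @param x numeric vector of observations.
#' @param p probability (or vector of probabilities) in (0, 1).
#' @return Numeric vector of quantile estimates, one per probability.
#' @examples
#' empirical_quantile(c(3, 1, 2), 0.5)  # 2
#' @export
empirical_quantile <- function(x, p) {
  if (length(x) < 1L) stop("empty sample")
  if (any(p <= 0) || any(p >= 1)) stop("'p' must lie in (0, 1)")
  sort(x)[ceiling(length(x) * p)]
}

#' Pooled quantile vector
#'
#' Group-major concatenation \eqn{\hat q = (\hat q_{11}, \dots, \hat q_{1m},
#' \hat q_{21}, \dots, \hat q_{km})'} of empirical quantiles.
#'
#' @param gs a `grouped_sample`.
#' @param spec a `quantile_spec`.
#' @return An object of class `quantile_estimates`: list with `values`
#'   (length `k * m`), `spec`, `k`.
#' @export
pooled_quantiles <- function(gs, spec) {
  stopifnot(inherits(gs, "grouped_sample"), inherits(spec, "quantile_spec"))
  values <- unlist(lapply(gs$groups, empirical_quantile, p = spec$p))
  names(values) <- paste0(rep(gs$labels, each = length(spec$p)), ":",
                          rep(spec$labels, gs$k))
  structure(list(values = values, spec = spec, k = gs$k),
            class = "quantile_estimates")
}

#' Rule-of-thumb bandwidth for kernel density estimation
#'
#' Silverman-style rule \eqn{0.9\, n^{-1/5} \min\{SD, IQR/1.34\}} (the
#' `nrd0` choice). Fallback chain when \eqn{\min\{SD, IQR/1.34\} = 0}:
#' use the SD; if the SD is also 0 (constant sample) return 1 with a
#' warning.
#'
#' @param x numeric vector with at least 2 observations.
#' @return A positive bandwidth.
#' @examples
#' bandwidth_nrd(rnorm(100))
#' @export
bandwidth_nrd <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations for a bandwidth")
  s <- stats::sd(x)
  lo <- min(s, stats::IQR(x) / 1.34)
  if (lo == 0) lo <- s
  if (lo == 0) {
    warning("constant sample: falling back to bandwidth scale 1")
    lo <- 1
  }
  0.9 * lo * n^(-0.2)
}

#' Gaussian kernel density estimate at given points
#'
#' \eqn{\hat f(u) = (n h)^{-1} \sum_s \varphi((u - x_s)/h)} with
#' \eqn{\varphi} the standard normal density; strictly positive everywhere.
#'
#' @param x numeric sample.
#' @param at evaluation point(s).
#' @param bw bandwidth (> 0); defaults to [bandwidth_nrd()].
#' @return Density estimate(s) at `at`.
#' @export
kernel_density_at <- function(x, at, bw = bandwidth_nrd(x)) {
  if (bw <= 0) stop("'bw' must be positive")
  vapply(at, function(u) mean(stats::dnorm((u - x) / bw)) / bw, numeric(1))
}

# min(pa, pb) - pa * pb matrix for a probability vector
.pmin_mat <- function(p) outer(p, p, pmin) - outer(p, p)

#' Covariance of the scaled pooled quantile vector
#'
#' Estimates the asymptotic covariance \eqn{\Sigma} of
#' \eqn{\sqrt n (\hat q - q)}, the block-diagonal (direct-sum) matrix with
#' group blocks
#' \deqn{\Sigma^{(i)}_{ab} = \kappa_i^{-1}
#'   \frac{\min\{p_a, p_b\} - p_a p_b}{f_i(q_{ia}) f_i(q_{ib})},}
#' \eqn{\kappa_i = n_i/n}. Three estimators are available:
#' \describe{
#'   \item{`kernel`}{Gaussian kernel plug-in density estimates at the
#'     empirical quantiles with the [bandwidth_nrd()] bandwidth.}
#'   \item{`bootstrap`}{Groupwise with-replacement resampling: the block is
#'     `n` times the empirical covariance of `B` resampled quantile
#'     vectors.}
#'   \item{`interval`}{Order-statistic interval estimator of the inverse
#'     density: with \eqn{\lambda = z_{1-\gamma/2}\sqrt{n_i p (1-p)}},
#'     \eqn{L = \max\{\lceil n_i p - \lambda\rceil, 1\}},
#'     \eqn{U = \min\{\lceil n_i p + \lambda\rceil, n_i\}},
#'     \eqn{1/\hat f_i(\hat q) = n_i (X_{(U)} - X_{(L)}) / (2\lambda)}.}
#' }
#'
#' @param gs a `grouped_sample`.
#' @param spec a `quantile_spec`.
#' @param method covariance estimator, one of `"kernel"`, `"bootstrap"`,
#'   `"interval"`.
#' @param B number of bootstrap replicates (bootstrap estimator only).
#' @param gamma interval level for the interval estimator (default 0.05).
#' @param seed optional seed for the bootstrap estimator.
#' @return An object of class `quantile_cov`: list with `blocks` (k
#'   matrices m x m), `full` (block-diagonal km x km matrix), `method`,
#'   `density_values` (kernel/interval), `settings`.
#' @examples
#' gs <- grouped_sample(list(rnorm(50), rnorm(60)))
#' quantile_cov(gs, quantile_spec(0.5))
#' @export
quantile_cov <- function(gs, spec, method = c("kernel", "bootstrap", "interval"),
                         B = 2000L, gamma = 0.05, seed = NULL) {
  stopifnot(inherits(gs, "grouped_sample"), inherits(spec, "quantile_spec"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  res <- .cov_blocks(gs$groups, gs$sizes, gs$n, spec$p, method,
                     B = B, gamma = gamma, labels = gs$labels)
  m <- length(spec$p)
  full <- matrix(0, gs$k * m, gs$k * m)
  for (i in seq_len(gs$k)) {
    idx <- (i - 1L) * m + seq_len(m)
    full[idx, idx] <- res$blocks[[i]]
  }
  structure(list(blocks = res$blocks, full = full, method = method,
                 density_values = res$density_values,
                 settings = list(B = if (method == "bootstrap") B else NULL,
                                 gamma = if (method == "interval") gamma else NULL,
                                 bandwidths = res$bandwidths, seed = seed),
                 k = gs$k, m = m),
            class = "quantile_cov")
}

#' @export
print.quantile_cov <- function(x, ...) {
  cat(sprintf("Quantile covariance estimate (%s): k = %d blocks of %d x %d\n",
              x$method, x$k, x$m, x$m))
  invisible(x)
}

# ---- lean internals shared by the public API and the resampling loops ----

# sorted-group quantiles, group-major vector
.grp_quantiles <- function(groups, p, presorted = FALSE) {
  unlist(lapply(groups, function(x) {
    if (!presorted) x <- sort.int(x, method = "radix")
    x[ceiling(length(x) * p)]
  }))
}

# interpolating type-7 quantile on a pre-sorted vector (matches stats::IQR)
.q7 <- function(sx, p) {
  n <- length(sx)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  sx[lo] + (h - lo) * (sx[pmin(lo + 1, n)] - sx[lo])
}

.sd_fast <- function(x, n) {
  mu <- sum(x) / n
  sqrt(sum((x - mu)^2) / (n - 1))
}

.bw_nrd <- function(sx, n) {
  s <- .sd_fast(sx, n)
  lo <- min(s, (.q7(sx, 0.75) - .q7(sx, 0.25)) / 1.34)
  if (lo == 0) lo <- s
  if (lo == 0) lo <- 1
  0.9 * lo * n^(-0.2)
}

# covariance blocks from raw group vectors; returns list(blocks,
# density_values, bandwidths). Throws informative errors on degeneracy.
# V = .pmin_mat(p) may be precomputed by hot loops; `presorted` skips the
# per-group sort when the caller already sorted each group.
.cov_blocks <- function(groups, sizes, n, p, method, B = 2000L, gamma = 0.05,
                        labels = NULL, V = NULL, presorted = FALSE) {
  k <- length(groups)
  m <- length(p)
  if (is.null(V)) V <- .pmin_mat(p)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  blocks <- vector("list", k)
  dens <- if (method != "bootstrap") matrix(NA_real_, k, m) else NULL
  bws <- if (method == "kernel") numeric(k) else NULL
  for (i in seq_len(k)) {
    ni <- sizes[i]
    sx <- if (presorted) groups[[i]] else sort.int(groups[[i]], method = "radix")
    if (method == "kernel") {
      if (ni < 2L) stop(sprintf("group %s: need >= 2 observations for the kernel estimator", labels[i]))
      qh <- sx[ceiling(ni * p)]
      h <- .bw_nrd(sx, ni)
      if (!is.finite(h) || h <= 0) {
        stop(sprintf("degenerate bandwidth in group %s", labels[i]))
      }
      f <- numeric(m)
      for (j in seq_len(m)) f[j] <- sum(stats::dnorm((qh[j] - sx) / h)) / (ni * h)
      blocks[[i]] <- (n / ni) * V / outer(f, f)
      dens[i, ] <- f
      bws[i] <- h
    } else if (method == "interval") {
      z <- stats::qnorm(1 - gamma / 2)
      lam <- z * sqrt(ni * p * (1 - p))
      L <- pmax(ceiling(ni * p - lam), 1)
      U <- pmin(ceiling(ni * p + lam), ni)
      if (any(L >= U)) {
        stop(sprintf("group %s: sample too small for the interval estimator", labels[i]))
      }
      width <- sx[U] - sx[L]
      if (any(width <= 0)) {
        stop(sprintf(paste0("group %s: tied order statistics make the interval ",
                            "estimator undefined (quantile density assumption ",
                            "implausible)"), labels[i]))
      }
      inv_f <- ni * width / (2 * lam)
      blocks[[i]] <- (n / ni) * V * outer(inv_f, inv_f)
      dens[i, ] <- 1 / inv_f
    } else { # bootstrap
      if (B < 2L) stop("'B' must be >= 2 for the bootstrap covariance estimator")
      qb <- matrix(NA_real_, B, m)
      for (b in seq_len(B)) {
        xb <- sort.int(sx[sample.int(ni, ni, replace = TRUE)], method = "radix")
        qb[b, ] <- xb[ceiling(ni * p)]
      }
      blk <- n * stats::cov(qb)
      if (any(diag(blk) <= 0)) {
        stop(sprintf(paste0("group %s: bootstrap quantiles are degenerate ",
                            "(all resample quantiles identical); increase the ",
                            "sample size or choose another covariance estimator"),
                     labels[i]))
      }
      blocks[[i]] <- blk
    }
  }
  list(blocks = blocks, density_values = dens, bandwidths = bws)
}

# block-diagonal quadratic forms h' Sigma h for all rows of H at once;
# blocks is a k-list of m x m matrices
.quad_forms <- function(H, blocks, k, m) {
  out <- numeric(nrow(H))
  for (i in seq_len(k)) {
    idx <- (i - 1L) * m + seq_len(m)
    Hi <- H[, idx, drop = FALSE]
    out <- out + rowSums((Hi %*% blocks[[i]]) * Hi)
  }
  out
}

# studentized statistics T = sqrt(n) (H qhat - margins) / sqrt(h' Sigma h)
.tstats <- function(H, qhat, blocks, n, margins, k, m) {
  denom2 <- .quad_forms(H, blocks, k, m)
  sqrt(n) * (as.vector(H %*% qhat) - margins) / sqrt(denom2)
}
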