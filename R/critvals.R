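# Empirical beta-quantile of a resampling distribution: the ceiling(B*beta)
# order statistic, identical convention across all resampling engines.
.resample_quantile <- function(v, beta) {
  B <- length(v)
  sort(v)[min(max(ceiling(B * beta), 1L), B)]
}

.new_crit <- function(values, method, alternative, alpha, draws = NULL,
                      B = NULL, M = NULL, seed = NULL,
                      diagnostics = NULL) {
  structure(list(values = values, method = method, alternative = alternative,
                 alpha = alpha, draws = draws, B = B, M = M, seed = seed,
                 diagnostics = diagnostics),
            class = "crit_values")
}

#' @export
print.crit_values <- function(x, ...) {
  cat(sprintf("Critical values (%s, %s, alpha = %g):\n",
              x$method, x$alternative, x$alpha))
  print(round(x$values, 4))
  invisible(x)
}

#' Bonferroni-adjusted asymptotic critical values
#'
#' Standard normal quantiles at the Bonferroni-corrected local level:
#' \eqn{z_{1-\alpha/(2r)}} for the two-sided problem,
#' \eqn{z_{1-\alpha/r}} for noninferiority.
#'
#' @param alpha global significance level in (0, 1).
#' @param r number of contrasts.
#' @param alternative `"two_sided"` or `"noninferiority"`.
#' @return A `crit_values` object with r identical entries.
#' @examples
#' crit_bonf_asymptotic(0.05, 1, "two_sided")       # 1.96
#' crit_bonf_asymptotic(0.05, 1, "noninferiority")  # 1.645
#' @export
crit_bonf_asymptotic <- function(alpha, r,
                                 alternative = c("two_sided", "noninferiority")) {
  alternative <- match.arg(alternative)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (r < 1L) stop("'r' must be >= 1")
  z <- if (alternative == "two_sided") stats::qnorm(1 - alpha / (2 * r))
       else stats::qnorm(1 - alpha / r)
  .new_crit(rep(z, r), "bonf-asymptotic", alternative, alpha)
}

#' Bonferroni-adjusted studentized permutation critical values
#'
#' Draws `B` permutations of the pooled sample (without replacement,
#' re-partitioned into the original group sizes), recomputes quantiles and
#' the chosen covariance estimator on every permuted data set (studentized
#' permutation -- this is what keeps the procedure asymptotically valid
#' without exchangeability), and forms the per-contrast statistics
#' \eqn{T^\pi_\ell = \sqrt n\, h_\ell' \hat q^\pi / \sqrt{h_\ell'
#' \hat\Sigma^\pi h_\ell}}. Per-contrast critical values are the empirical
#' \eqn{1 - \alpha/r} quantile of \eqn{\{T^\pi_{\ell,b}\}} (noninferiority)
#' or of \eqn{\{|T^\pi_{\ell,b}|\}} (two-sided). Under exchangeability
#' (equal group distributions) the resulting test is finitely exact.
#'
#' @param gs a `grouped_sample`.
#' @param spec a `quantile_spec`.
#' @param family a `contrast_family`.
#' @param alpha global level.
#' @param B number of permutations.
#' @param seed optional seed (set once before the permutation loop).
#' @param cov_method covariance estimator recomputed per permutation.
#' @param alternative `"two_sided"` or `"noninferiority"`.
#' @param B_cov inner bootstrap replicates when `cov_method = "bootstrap"`.
#' @param gamma interval level when `cov_method = "interval"`.
#' @return A `crit_values` object; `draws` holds the r x B matrix of
#'   retained permutation statistics (raw, unsigned), `diagnostics` the
#'   attempted/dropped replicate counts.
#' @export
crit_bonf_permutation <- function(gs, spec, family, alpha = 0.05, B = 1999L,
                                  seed = NULL,
                                  cov_method = c("kernel", "bootstrap", "interval"),
                                  alternative = c("two_sided", "noninferiority"),
                                  B_cov = 100L, gamma = 0.05) {
  cov_method <- match.arg(cov_method)
  alternative <- match.arg(alternative)
  if (B < 1L) stop("'B' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pooled <- unlist(gs$groups)
  sizes <- gs$sizes
  k <- gs$k
  m <- length(spec$p)
  n <- gs$n
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  r <- nrow(family$H)
  H <- family$H
  V <- .pmin_mat(spec$p)
  draws <- matrix(NA_real_, r, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    groups_b <- lapply(seq_len(k), function(i) {
      sort.int(pooled[perm[starts[i]:ends[i]]], method = "radix")
    })
    tb <- tryCatch({
      qh <- .grp_quantiles(groups_b, spec$p, presorted = TRUE)
      blocks <- .cov_blocks(groups_b, sizes, n, spec$p, cov_method,
                            B = B_cov, gamma = gamma, V = V,
                            presorted = TRUE)$blocks
      .tstats(H, qh, blocks, n, 0, k, m)
    }, error = function(e) NULL)
    if (is.null(tb) || any(!is.finite(tb))) {
      dropped <- dropped + 1L
    } else {
      draws[, b] <- tb
    }
  }
  if (dropped > 0.1 * B) {
    stop(sprintf("permutation: %d of %d replicates degenerate (> 10%%)",
                 dropped, B))
  }
  keep <- draws[, colSums(is.na(draws)) == 0L, drop = FALSE]
  beta <- 1 - alpha / r
  vals <- apply(if (alternative == "two_sided") abs(keep) else keep, 1L,
                .resample_quantile, beta = beta)
  .new_crit(stats::setNames(vals, family$row_labels), "bonf-permutation",
            alternative, alpha, draws = keep, B = B, seed = seed,
            diagnostics = list(attempted = B, dropped = dropped))
}

# block-diagonal factor A with A A' = Sigma, via per-block eigendecomposition
# (PSD-safe: negative eigenvalues within tolerance are clipped to zero)
.cov_factor <- function(cov) {
  m <- cov$m
  A <- matrix(0, cov$k * m, cov$k * m)
  for (i in seq_len(cov$k)) {
    blk <- (cov$blocks[[i]] + t(cov$blocks[[i]])) / 2
    ev <- eigen(blk, symmetric = TRUE)
    lam <- ev$values
    if (any(lam < -1e-8 * max(abs(lam), 1))) {
      stop("covariance block is not positive semi-definite")
    }
    idx <- (i - 1L) * m + seq_len(m)
    A[idx, idx] <- ev$vectors %*% (sqrt(pmax(lam, 0)) * t(ev$vectors))
  }
  A
}

#' Asymptotic MCTP critical value (max of correlated normals)
#'
#' Approximates, by Monte Carlo, the \eqn{1-\alpha} quantile of
#' \eqn{\max_\ell Y_\ell} (noninferiority) or \eqn{\max_\ell |Y_\ell|}
#' (two-sided), where \eqn{(Y_1, \dots, Y_r)' \sim N(0, \hat D H \hat\Sigma
#' H' \hat D)}. Draws are generated through a factor of the block-diagonal
#' \eqn{\hat\Sigma} (never an inverse of the correlation matrix), so
#' rank-deficient families such as Tukey work without regularization. One
#' common critical value is returned for all r contrasts.
#'
#' @param family a `contrast_family`.
#' @param cov a `quantile_cov` with matching dimensions.
#' @param alpha global level.
#' @param alternative `"two_sided"` or `"noninferiority"`.
#' @param M number of Monte Carlo draws (>= 1000).
#' @param seed optional seed.
#' @return A `crit_values` object; `draws` holds the M max-statistics.
#' @examples
#' gs <- grouped_sample(list(rnorm(40), rnorm(40), rnorm(40)))
#' sp <- quantile_spec(0.5)
#' crit_mctp_asymptotic(contrast_dunnett(3), quantile_cov(gs, sp), M = 5000)
#' @export
crit_mctp_asymptotic <- function(family, cov, alpha = 0.05,
                                 alternative = c("two_sided", "noninferiority"),
                                 M = 1e5, seed = NULL) {
  alternative <- match.arg(alternative)
  if (M < 1000) stop("'M' must be >= 1000")
  M <- as.integer(M)
  if (!is.null(seed)) set.seed(seed)
  H <- family$H
  km <- ncol(H)
  denom2 <- .quad_forms(H, cov$blocks, cov$k, cov$m)
  if (any(denom2 <= 0)) stop("degenerate covariance: non-positive studentizer")
  A <- .cov_factor(cov)
  G <- (1 / sqrt(denom2)) * (H %*% A)   # rows scaled by D-hat
  # Y (r x M) in manageable chunks to bound memory at large M
  chunk <- max(1L, min(M, as.integer(2e7 / km)))
  maxdraws <- numeric(M)
  done <- 0L
  while (done < M) {
    nb <- min(chunk, M - done)
    Y <- G %*% matrix(stats::rnorm(km * nb), km, nb)
    if (alternative == "two_sided") Y <- abs(Y)
    maxdraws[done + seq_len(nb)] <- apply(Y, 2L, max)
    done <- done + nb
  }
  q <- .resample_quantile(maxdraws, 1 - alpha)
  .new_crit(stats::setNames(rep(q, nrow(H)), family$row_labels),
            "mctp-asymptotic", alternative, alpha, draws = maxdraws,
            M = M, seed = seed)
}

#' Groupwise bootstrap MCTP critical value
#'
#' For each of `B` replicates, every group is resampled with replacement
#' (its own size), then the bootstrap counterparts of the studentized
#' statistics
#' \eqn{T^*_\ell = \sqrt n\, h_\ell'(\hat q^* - \hat q) / \sqrt{h_\ell'
#' \hat\Sigma^* h_\ell}} are computed with the chosen covariance estimator
#' recomputed on the bootstrap sample. The common critical value is the
#' empirical \eqn{1-\alpha} quantile of \eqn{\max_\ell T^*_\ell}
#' (noninferiority) or \eqn{\max_\ell |T^*_\ell|} (two-sided).
#'
#' @inheritParams crit_bonf_permutation
#' @return A `crit_values` object; `draws` holds the retained max-statistic
#'   replicates, `diagnostics` the attempted/dropped counts.
#' @export
crit_mctp_bootstrap <- function(gs, spec, family, alpha = 0.05, B = 1999L,
                                seed = NULL,
                                cov_method = c("kernel", "bootstrap", "interval"),
                                alternative = c("two_sided", "noninferiority"),
                                B_cov = 100L, gamma = 0.05) {
  cov_method <- match.arg(cov_method)
  alternative <- match.arg(alternative)
  if (B < 1L) stop("'B' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- gs$k
  m <- length(spec$p)
  n <- gs$n
  sizes <- gs$sizes
  H <- family$H
  qhat <- .grp_quantiles(gs$groups, spec$p)
  V <- .pmin_mat(spec$p)
  maxdraws <- rep(NA_real_, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    groups_b <- lapply(seq_len(k), function(i) {
      sort.int(gs$groups[[i]][sample.int(sizes[i], sizes[i], replace = TRUE)],
               method = "radix")
    })
    tb <- tryCatch({
      qstar <- .grp_quantiles(groups_b, spec$p, presorted = TRUE)
      blocks <- .cov_blocks(groups_b, sizes, n, spec$p, cov_method,
                            B = B_cov, gamma = gamma, V = V,
                            presorted = TRUE)$blocks
      sqrt(n) * as.vector(H %*% (qstar - qhat)) /
        sqrt(.quad_forms(H, blocks, k, m))
    }, error = function(e) NULL)
    if (is.null(tb) || any(!is.finite(tb))) {
      dropped <- dropped + 1L
    } else {
      maxdraws[b] <- if (alternative == "two_sided") max(abs(tb)) else max(tb)
    }
  }
  if (dropped > 0.1 * B) {
    stop(sprintf("bootstrap: %d of %d replicates degenerate (> 10%%)",
                 dropped, B))
  }
  keep <- maxdraws[!is.na(maxdraws)]
  q <- .resample_quantile(keep, 1 - alpha)
  .new_crit(stats::setNames(rep(q, nrow(H)), family$row_labels),
            "mctp-bootstrap", alternative, alpha, draws = keep, B = B,
            seed = seed, diagnostics = list(attempted = B, dropped = dropped))
}
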