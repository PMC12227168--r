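#' Studentized contrast statistics
#'
#' Computes the per-contrast statistics
#' \deqn{T_n(h_\ell, \varepsilon_\ell) = \sqrt{n}\,(h_\ell' \hat q -
#'   \varepsilon_\ell) / \sqrt{h_\ell' \hat\Sigma h_\ell},}
#' together with the scaling diagonal
#' \eqn{\hat D = \mathrm{diag}\{(h_\ell' \hat\Sigma h_\ell)^{-1/2}\}} and the
#' estimated correlation \eqn{\hat R = \hat D H \hat\Sigma H' \hat D} of the
#' joint limit. Each statistic is asymptotically standard normal under its
#' local null; for a single contrast \eqn{T_n^2(h, 0)} is the quantile-ANOVA
#' Wald statistic of the one-row hypothesis.
#'
#' @param gs a `grouped_sample`.
#' @param spec a `quantile_spec` (must match the family's `m`).
#' @param family a `contrast_family`.
#' @param cov a `quantile_cov` computed on `gs` with the same `spec`.
#' @param margins optional margins overriding `family$margins`.
#' @return An object of class `stat_bundle`: list with `statistics`
#'   (length r), `scale` (diagonal of \eqn{\hat D}), `correlation`
#'   (r x r), `quantiles` (`quantile_estimates`), `n`, `margins`,
#'   `family`, `cov`.
#' @examples
#' gs <- grouped_sample(list(rnorm(30), rnorm(30, 1)))
#' sp <- quantile_spec(0.5)
#' fam <- contrast_dunnett(2)
#' studentized_contrasts(gs, sp, fam, quantile_cov(gs, sp))
#' @export
studentized_contrasts <- function(gs, spec, family, cov, margins = NULL) {
  stopifnot(inherits(gs, "grouped_sample"), inherits(spec, "quantile_spec"),
            inherits(family, "contrast_family"), inherits(cov, "quantile_cov"))
  m <- length(spec$p)
  if (family$m != m) stop("family and quantile spec disagree on m")
  if (family$k != gs$k) stop("family and sample disagree on k")
  if (cov$k != gs$k || cov$m != m) stop("covariance estimate has wrong dimensions")
  if (is.null(margins)) margins <- family$margins
  if (length(margins) == 1L) margins <- rep(margins, nrow(family$H))

  qhat <- pooled_quantiles(gs, spec)
  H <- family$H
  denom2 <- .quad_forms(H, cov$blocks, gs$k, m)
  if (any(!is.finite(denom2)) || any(denom2 <= 0)) {
    bad <- which(!is.finite(denom2) | denom2 <= 0)
    stop(sprintf("non-positive studentizer for contrast(s): %s",
                 paste(family$row_labels[bad], collapse = ", ")))
  }
  tn <- sqrt(gs$n) * (as.vector(H %*% qhat$values) - margins) / sqrt(denom2)
  corr <- .correlation_from(H, cov$full, denom2)
  structure(list(statistics = stats::setNames(tn, family$row_labels),
                 scale = 1 / sqrt(denom2), correlation = corr,
                 quantiles = qhat, n = gs$n, margins = margins,
                 family = family, cov = cov),
            class = "stat_bundle")
}

.correlation_from <- function(H, full, denom2 = NULL) {
  HS <- H %*% full %*% t(H)
  if (is.null(denom2)) denom2 <- diag(HS)
  d <- 1 / sqrt(denom2)
  corr <- d * HS * rep(d, each = nrow(HS))
  diag(corr) <- 1
  (corr + t(corr)) / 2
}

#' Estimated correlation of the contrast statistics
#'
#' Returns \eqn{\hat R = \hat D H \hat\Sigma H' \hat D}, the correlation
#' matrix of the joint normal limit of the studentized contrasts. Has a unit
#' diagonal by construction; may be rank-deficient for overcomplete families
#' (e.g. Tukey), which is handled downstream by sampling through a factor of
#' \eqn{\hat\Sigma} rather than inverting \eqn{\hat R}.
#'
#' @param family a `contrast_family`.
#' @param cov a `quantile_cov` with matching dimensions.
#' @return An r x r correlation matrix.
#' @export
contrast_correlation <- function(family, cov) {
  stopifnot(inherits(family, "contrast_family"), inherits(cov, "quantile_cov"))
  denom2 <- .quad_forms(family$H, cov$blocks, cov$k, cov$m)
  if (any(denom2 <= 0)) stop("non-positive studentizer; degenerate covariance")
  .correlation_from(family$H, cov$full, denom2)
}

#' @export
print.stat_bundle <- function(x, ...) {
  cat("Studentized quantile contrasts (n =", x$n, ")\n")
  print(round(x$statistics, 4))
  invisible(x)
}
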