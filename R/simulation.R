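# supported generator distributions and their exact medians / quantiles
.dist_tags <- c("normal", "lognormal", "chisq3", "t2", "t3")

.dist_quantile <- function(distribution, p) {
  switch(distribution,
         normal = stats::qnorm(p),
         lognormal = stats::qlnorm(p),
         chisq3 = stats::qchisq(p, df = 3),
         t2 = stats::qt(p, df = 2),
         t3 = stats::qt(p, df = 3),
         stop("unknown distribution tag: ", distribution))
}

.dist_draw <- function(distribution, n) {
  switch(distribution,
         normal = stats::rnorm(n),
         lognormal = stats::rlnorm(n),
         chisq3 = stats::rchisq(n, df = 3),
         t2 = stats::rt(n, df = 2),
         t3 = stats::rt(n, df = 3),
         stop("unknown distribution tag: ", distribution))
}

#' Generate grouped data from the location-scale model
#'
#' Draws \eqn{X_{is} = \sigma_i (\eta_{is} - m_i) + \mu_i}, where the
#' \eqn{\eta_{is}} are i.i.d. from the named base distribution and
#' \eqn{m_i} is that distribution's exact median (computed from the inverse
#' CDF, not estimated). The population median of group i is therefore
#' exactly \eqn{\mu_i}, for every base distribution and scale.
#'
#' @param sizes group sizes \eqn{n_1, \dots, n_k}.
#' @param distribution one of `"normal"`, `"lognormal"` (log-normal(0,1)),
#'   `"chisq3"` (chi-squared, 3 df), `"t2"`, `"t3"` (t with 2 / 3 df).
#' @param sigma positive scales, recycled to k.
#' @param mu location shifts, recycled to k.
#' @param seed optional seed.
#' @return A `grouped_sample`.
#' @examples
#' generate_group_sample(c(15, 15, 15, 15), "lognormal", seed = 1)
#' @export
generate_group_sample <- function(sizes, distribution = "normal", sigma = 1,
                                  mu = 0, seed = NULL) {
  distribution <- match.arg(distribution, .dist_tags)
  k <- length(sizes)
  sigma <- rep_len(sigma, k)
  mu <- rep_len(mu, k)
  if (any(sigma <= 0)) stop("all scales must be positive")
  if (!is.null(seed)) set.seed(seed)
  med <- .dist_quantile(distribution, 0.5)
  groups <- lapply(seq_len(k), function(i) {
    sigma[i] * (.dist_draw(distribution, sizes[i]) - med) + mu[i]
  })
  grouped_sample(groups)
}

#' Scenario configuration for the simulation engine
#'
#' @param sizes group sizes.
#' @param distribution base distribution tag (see
#'   [generate_group_sample()]).
#' @param sigma scales (recycled).
#' @param mu shifts (recycled); population group medians.
#' @param contrast contrast family tag (`"dunnett"`, `"tukey"`,
#'   `"grandmean"`).
#' @param base base group for Dunnett contrasts.
#' @param alternative `"two_sided"` or `"noninferiority"`.
#' @param alpha global level.
#' @param Nsim simulation replicates.
#' @param B resampling iterations per replicate.
#' @param cov_method covariance estimator.
#' @param label optional scenario label.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(sizes, distribution = "normal", sigma = 1, mu = 0,
                            contrast = "dunnett", base = 1L,
                            alternative = "two_sided", alpha = 0.05,
                            Nsim = 5000L, B = 2000L, cov_method = "kernel",
                            label = NULL) {
  k <- length(sizes)
  distribution <- match.arg(distribution, .dist_tags)
  sigma <- rep_len(sigma, k)
  mu <- rep_len(mu, k)
  if (any(sigma <= 0)) stop("all scales must be positive")
  if (Nsim < 1L) stop("'Nsim' must be >= 1")
  if (is.null(label)) {
    label <- sprintf("%s/%s/%s/n=%s", distribution, contrast, alternative,
                     paste(sizes, collapse = "-"))
  }
  structure(list(sizes = as.integer(sizes), distribution = distribution,
                 sigma = sigma, mu = mu, contrast = contrast,
                 base = as.integer(base), alternative = alternative,
                 alpha = alpha, Nsim = as.integer(Nsim), B = as.integer(B),
                 cov_method = cov_method, label = label),
            class = "scenario_config")
}

#' Small-sample simulation grid
#'
#' Reconstructs the 120-cell small-sample study: k = 4 groups, medians
#' (p = 0.5), the four (sizes, scales) pairings
#' \itemize{
#'   \item balanced homoskedastic: n = (15,15,15,15), sigma = (1,1,1,1)
#'   \item balanced heteroskedastic: n = (15,15,15,15),
#'     sigma = (1,1.25,1.5,1.75)
#'   \item unbalanced, positive pairing: n = (10,10,20,20),
#'     sigma = (1,1.25,1.5,1.75)
#'   \item unbalanced, negative pairing: n = (10,10,20,20),
#'     sigma = (1.75,1.5,1.25,1)
#' }
#' crossed with 5 base distributions, 3 contrast families (Dunnett base 1,
#' Tukey, grand-mean) and 2 hypothesis types, all margins 0. Under the
#' null all shifts are 0; `delta > 0` adds the shift to group 4 (power
#' grid).
#'
#' @param delta shift added to group 4 (0 for the null grid; the power
#'   study uses 0.5, 1, 1.5).
#' @param Nsim,B,alpha defaults for every cell.
#' @return List of `scenario_config` (120 cells).
#' @export
small_sample_grid <- function(delta = 0, Nsim = 5000L, B = 2000L,
                              alpha = 0.05) {
  n1 <- c(15L, 15L, 15L, 15L)
  n2 <- c(10L, 10L, 20L, 20L)
  s1 <- c(1, 1, 1, 1)
  s2 <- c(1, 1.25, 1.5, 1.75)
  s3 <- c(1.75, 1.5, 1.25, 1)
  pairings <- list(list(n = n1, s = s1, tag = "balanced-homo"),
                   list(n = n1, s = s2, tag = "balanced-hetero"),
                   list(n = n2, s = s2, tag = "positive-pairing"),
                   list(n = n2, s = s3, tag = "negative-pairing"))
  out <- list()
  for (pr in pairings) {
    for (dist in .dist_tags) {
      for (fam in c("dunnett", "tukey", "grandmean")) {
        for (alt in c("two_sided", "noninferiority")) {
          out[[length(out) + 1L]] <- scenario_config(
            sizes = pr$n, distribution = dist, sigma = pr$s,
            mu = c(0, 0, 0, delta), contrast = fam, base = 1L,
            alternative = alt, alpha = alpha, Nsim = Nsim, B = B,
            label = sprintf("%s/%s/%s/%s/delta=%g", pr$tag, dist, fam, alt,
                            delta))
        }
      }
    }
  }
  out
}

#' Data-example-motivated simulation grid
#'
#' k = 17 groups with the heterogeneous sizes n = (59, 175, 98, 78, 280,
#' 176, 351, 128, 368, 403, 240, 376, 278, 549, 428, 379, 250), Dunnett
#' contrasts with group 17 as base (r = 16 tests), margins 0, four base
#' distributions (t2 is excluded: it has no finite variance, so scales
#' cannot be matched to empirical group variances), both hypothesis types.
#' The scales and shifts are user-supplied, since in the motivating study
#' they are derived from the (external) hatch-date data.
#'
#' @param sigma length-17 positive scales.
#' @param mu length-17 shifts (0 under the null).
#' @param Nsim,B,alpha defaults for every cell.
#' @return List of `scenario_config` (8 cells).
#' @export
data_example_grid <- function(sigma, mu = rep(0, 17), Nsim = 5000L,
                              B = 2000L, alpha = 0.05) {
  sizes <- c(59L, 175L, 98L, 78L, 280L, 176L, 351L, 128L, 368L, 403L, 240L,
             376L, 278L, 549L, 428L, 379L, 250L)
  if (length(sigma) != 17L || length(mu) != 17L) {
    stop("'sigma' and 'mu' must have length 17")
  }
  out <- list()
  for (dist in setdiff(.dist_tags, "t2")) {
    for (alt in c("two_sided", "noninferiority")) {
      out[[length(out) + 1L]] <- scenario_config(
        sizes = sizes, distribution = dist, sigma = sigma, mu = mu,
        contrast = "dunnett", base = 17L, alternative = alt, alpha = alpha,
        Nsim = Nsim, B = B,
        label = sprintf("data-example/%s/%s", dist, alt))
    }
  }
  out
}

#' Run a simulation scenario
#'
#' For each of `Nsim` replicates: generate a data set from the scenario's
#' location-scale model, run each requested testing method, and record the
#' local rejections. Summaries: the empirical FWER is the fraction of
#' replicates with at least one rejection of a true local null; the
#' empirical global power is the fraction of replicates rejecting the
#' global null (any rejection); local power is reported per false
#' contrast. Truth status is computed from the exact population quantiles
#' of the location-scale model, not estimated. Monte-Carlo standard errors
#' are \eqn{\sqrt{\hat p (1 - \hat p) / N_{sim}}}.
#'
#' @param cfg a `scenario_config`.
#' @param methods character vector of testing methods (see [qmctp()]).
#' @param Nsim,B overrides of the scenario defaults.
#' @param seed master seed; per-replicate seeds are derived from it, so
#'   results do not depend on the method list evaluated.
#' @param M Monte-Carlo draws for `mctp-asymptotic`.
#' @param B_cov inner bootstrap size for the bootstrap covariance
#'   estimator.
#' @param probs probabilities of interest (default the median, as in the
#'   small-sample and data-example grids).
#' @return A `data.frame` (class `scenario_summary`) with one row per
#'   method: `fwer`, `fwer_se`, `global_power`, `global_power_se`,
#'   `Nsim`, `failures`; per-contrast local power in
#'   `attr(, "local_power")`, truth status in `attr(, "true_null")`.
#' @export
run_scenario <- function(cfg, methods = "bonf-permutation", Nsim = cfg$Nsim,
                         B = cfg$B, seed = NULL, M = 1e4, B_cov = 100L,
                         probs = 0.5) {
  stopifnot(inherits(cfg, "scenario_config"))
  spec <- if (inherits(probs, "quantile_spec")) probs else quantile_spec(probs)
  k <- length(cfg$sizes)
  family <- .build_family(cfg$contrast, k, cfg$base, 0)
  r <- nrow(family$H)

  # exact population quantiles of X_i under the location-scale model
  qpop <- unlist(lapply(seq_len(k), function(i) {
    cfg$sigma[i] * (.dist_quantile(cfg$distribution, spec$p) -
                      .dist_quantile(cfg$distribution, 0.5)) + cfg$mu[i]
  }))
  true_val <- as.vector(family$H %*% qpop)
  true_null <- if (cfg$alternative == "two_sided") {
    abs(true_val - family$margins) < 1e-12
  } else {
    true_val <= family$margins + 1e-12
  }

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, Nsim)
  rejections <- array(FALSE, dim = c(length(methods), Nsim, r),
                      dimnames = list(methods, NULL, family$row_labels))
  failures <- stats::setNames(integer(length(methods)), methods)
  for (s in seq_len(Nsim)) {
    set.seed(rep_seeds[s])
    gs <- generate_group_sample(cfg$sizes, cfg$distribution, cfg$sigma,
                                cfg$mu)
    for (mi in seq_along(methods)) {
      res <- tryCatch(
        .qmct_core(gs, spec, family, cfg$alternative, methods[mi],
                   cfg$cov_method, cfg$alpha, B, M, B_cov, 0.05)$reject,
        error = function(e) NULL)
      if (is.null(res)) {
        failures[mi] <- failures[mi] + 1L
      } else {
        rejections[mi, s, ] <- res
      }
    }
  }
  if (any(failures > 0.01 * Nsim)) {
    stop(sprintf("scenario aborted: > 1%% replicate failures (%s)",
                 paste(sprintf("%s: %d", methods, failures), collapse = ", ")))
  }

  fwer <- global_power <- rep(NA_real_, length(methods))
  local_power <- matrix(NA_real_, length(methods), r,
                        dimnames = list(methods, family$row_labels))
  for (mi in seq_along(methods)) {
    rej <- rejections[mi, , , drop = FALSE]
    dim(rej) <- c(Nsim, r)
    global_power[mi] <- mean(apply(rej, 1L, any))
    if (any(true_null)) {
      fwer[mi] <- mean(apply(rej[, true_null, drop = FALSE], 1L, any))
    }
    if (any(!true_null)) {
      local_power[mi, !true_null] <- colMeans(rej[, !true_null, drop = FALSE])
    }
  }
  out <- data.frame(method = methods, fwer = fwer,
                    fwer_se = sqrt(fwer * (1 - fwer) / Nsim),
                    global_power = global_power,
                    global_power_se = sqrt(global_power * (1 - global_power) / Nsim),
                    Nsim = Nsim, failures = as.integer(failures),
                    stringsAsFactors = FALSE)
  attr(out, "local_power") <- local_power
  attr(out, "true_null") <- true_null
  attr(out, "label") <- cfg$label
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' Synthetic 17-group fixture data set
#'
#' Emits a synthetic long-format data set with 17 skewed, heteroskedastic,
#' heavy-tailed groups whose sizes mimic a multi-year field study. Purely
#' synthetic (log-normal base draws with varying scale and shift); intended
#' for documentation and tests, not as a stand-in for any real data.
#'
#' @param seed seed for reproducibility.
#' @return A `data.frame` with columns `group` and `value`.
#' @export
synthetic_hatch_fixture <- function(seed = 1L) {
  sizes <- c(59L, 175L, 98L, 78L, 280L, 176L, 351L, 128L, 368L, 403L, 240L,
             376L, 278L, 549L, 428L, 379L, 250L)
  set.seed(seed)
  sigma <- stats::runif(17, 4, 9)
  mu <- stats::runif(17, 120, 145)
  gs <- generate_group_sample(sizes, "lognormal", sigma = sigma, mu = mu)
  data.frame(group = rep(paste0("year", sprintf("%02d", 6:22)), sizes),
             value = round(unlist(gs$groups), 2),
             stringsAsFactors = FALSE)
}
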