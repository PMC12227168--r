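test_that("margins equal to estimates give zero statistics and no rejections", {
  gs <- toy_sample(k = 3)
  sp <- quantile_spec(0.5)
  fam <- contrast_tukey(3)
  est <- as.vector(fam$H %*% pooled_quantiles(gs, sp)$values)
  res <- qmctp(gs, contrast = fam, margins = est,
               method = "bonf-asymptotic")
  expect_equal(res$table$statistic, rep(0, 3))
  expect_false(any(res$table$reject))
  expect_false(res$global_rejected)
})

test_that("global decision is the OR of the local decisions", {
  set.seed(23)
  for (rep in 1:10) {
    gs <- grouped_sample(lapply(1:3, function(i) rnorm(20, mean = i * 0.7)))
    res <- qmctp(gs, contrast = "tukey",
                 method = sample(c("bonf-asymptotic", "mctp-asymptotic"), 1),
                 M = 2000, seed = rep)
    expect_equal(res$global_rejected, any(res$table$reject))
  }
})

test_that("rejection is exactly dual to the margin lying outside the SCI", {
  set.seed(29)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    gs <- grouped_sample(lapply(seq_len(k), function(i)
      rnorm(sample(12:30, 1), mean = runif(1, -1, 1))))
    alt <- sample(c("two_sided", "noninferiority"), 1)
    dir <- sample(c("greater", "less"), 1)
    mth <- sample(c("bonf-asymptotic", "bonf-permutation",
                    "mctp-asymptotic"), 1)
    mg <- round(runif(1, -0.5, 0.5), 2)
    res <- qmctp(gs, contrast = "dunnett", margins = mg, alternative = alt,
                 direction = dir, method = mth, B = 200, M = 2000,
                 seed = rep)
    tab <- res$table
    outside <- tab$margin < tab$lower | tab$margin > tab$upper
    expect_equal(tab$reject, outside,
                 label = paste("duality", alt, dir, mth))
  }
})

test_that("adjusted p-values are consistent with decisions at level alpha", {
  set.seed(37)
  for (mth in c("bonf-asymptotic", "bonf-permutation", "mctp-asymptotic",
                "mctp-bootstrap")) {
    for (rep in 1:5) {
      gs <- grouped_sample(lapply(1:3, function(i)
        rnorm(18, mean = (i - 1) * runif(1, 0, 1.2))))
      alt <- if (rep %% 2) "two_sided" else "noninferiority"
      res <- qmctp(gs, contrast = "dunnett", alternative = alt,
                   method = mth, B = 400, M = 5000, seed = rep)
      # agreement up to resampling granularity: skip p-values within
      # 1.5/(B+1) of alpha where the order-statistic rule and the add-one
      # p-value can disagree by construction
      gran <- if (mth %in% c("bonf-permutation", "mctp-bootstrap")) {
        nrow(res$table) * 1.5 / 401
      } else if (mth == "mctp-asymptotic") 1.5 / 5000 else 0
      clear <- abs(res$table$p_adj - res$alpha) > gran
      expect_equal(res$table$reject[clear],
                   (res$table$p_adj <= res$alpha)[clear],
                   label = paste("p-decision", mth, alt))
      expect_true(all(res$table$p_adj >= 0 & res$table$p_adj <= 1))
    }
  }
})

test_that("many-to-one noninferiority with base = last group mirrors correctly", {
  # H0: m_base - m_l >= 7, i.e. with rows m_l - m_base: direction 'less',
  # margin -7 ... equivalently rows built as base-minus-l with margin 7.
  set.seed(41)
  gs <- grouped_sample(lapply(1:17, function(i) rnorm(40, mean = i / 4)))
  fam <- contrast_dunnett(17, base = 17)
  # contrasts give m_l - m_17; 'm_17 - m_l >= 7' is h'q <= -7, so test
  # h'q > -7 (direction greater, margin -7)
  res <- qmctp(gs, contrast = fam, margins = -7,
               alternative = "noninferiority", direction = "greater",
               method = "bonf-asymptotic")
  expect_equal(nrow(res$table), 16)
  expect_true(all(is.finite(res$table$lower)))
  expect_true(all(res$table$upper == Inf))

  # the mirrored formulation: negated rows (m_17 - m_l), margin +7,
  # direction 'less' gives identical decisions and (-inf, upper] bounds
  fam_m <- contrast_custom(-fam$H, k = 17)
  res_m <- qmctp(gs, contrast = fam_m, margins = 7,
                 alternative = "noninferiority", direction = "less",
                 method = "bonf-asymptotic")
  expect_equal(res_m$table$reject, res$table$reject)
  expect_true(all(res_m$table$lower == -Inf))
  expect_equal(res_m$table$upper, -res$table$lower)
  expect_equal(res_m$table$estimate, -res$table$estimate)
})

test_that("location shifts leave median-contrast decisions unchanged", {
  set.seed(43)
  x <- lapply(1:4, function(i) rlnorm(25))
  res1 <- qmctp(grouped_sample(x), contrast = "tukey",
                method = "bonf-asymptotic")
  res2 <- qmctp(grouped_sample(lapply(x, `+`, 100)), contrast = "tukey",
                method = "bonf-asymptotic")
  expect_equal(res2$table$statistic, res1$table$statistic, tolerance = 1e-8)
  expect_equal(res2$table$reject, res1$table$reject)
})

test_that("asymptotic MCTP rejects whenever Bonferroni-asymptotic rejects", {
  set.seed(47)
  for (rep in 1:10) {
    gs <- grouped_sample(lapply(1:4, function(i) rnorm(20, mean = i / 3)))
    # share the covariance estimate through a fixed seed
    bf <- qmctp(gs, contrast = "dunnett", method = "bonf-asymptotic",
                seed = 1)
    mc <- qmctp(gs, contrast = "dunnett", method = "mctp-asymptotic",
                M = 5e4, seed = 1)
    expect_true(all(mc$table$reject >= bf$table$reject))
  }
})

test_that("TOST equivalence behaves at the margin extremes", {
  set.seed(53)
  gs <- grouped_sample(lapply(1:3, function(i) rnorm(40)))
  # huge delta: equivalence concluded everywhere
  big <- qmctp_equivalence(gs, contrast = "tukey", delta = 1e6,
                           method = "bonf-asymptotic")
  expect_true(all(big$table$equivalent))
  expect_true(big$global_equivalent)
  # tiny delta: never concluded
  tiny <- qmctp_equivalence(gs, contrast = "tukey", delta = 1e-8,
                            method = "bonf-asymptotic")
  expect_false(any(tiny$table$equivalent))
  # one-sided runs are at the halved level
  expect_equal(big$lower_run$alpha, 0.025)
})

test_that("TOST decisions are invariant under sign flip of data and contrasts", {
  # odd group sizes keep the type-1 median exactly antisymmetric
  set.seed(59)
  x <- lapply(1:3, function(i) rnorm(31, mean = i / 10))
  fam <- contrast_tukey(3)
  fam_neg <- contrast_custom(-fam$H, k = 3)
  for (rep in 1:5) {
    d <- runif(1, 0.3, 2)
    a <- qmctp_equivalence(grouped_sample(x), contrast = fam, delta = d,
                           method = "bonf-asymptotic")
    b <- qmctp_equivalence(grouped_sample(lapply(x, function(v) -v)),
                           contrast = fam_neg, delta = d,
                           method = "bonf-asymptotic")
    expect_equal(a$table$equivalent, b$table$equivalent)
    expect_equal(b$table$estimate, a$table$estimate, tolerance = 1e-12)
  }
})
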