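test_that("empirical quantile is the left-continuous inverse", {
  expect_equal(empirical_quantile(c(3, 1, 2), 0.5), 2)
  expect_equal(empirical_quantile(c(1, 2, 3, 4), 0.5), 2)
  expect_equal(empirical_quantile(c(1, 2, 3, 4), 0.75), 3)
  expect_equal(empirical_quantile(5, 0.9), 5)
  # agrees with the type-1 sample quantile for random inputs
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(sample(3:40, 1))
    p <- runif(3, 0.05, 0.95)
    expect_equal(empirical_quantile(x, p),
                 unname(quantile(x, p, type = 1)))
  }
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
  expect_error(empirical_quantile(1:3, 1.2), "0, 1")
})

test_that("pooled quantile vector is group-major and order-invariant", {
  gs <- grouped_sample(list(c(1, 2, 3), c(4, 5, 6)))
  q <- pooled_quantiles(gs, quantile_spec(0.5))
  expect_equal(unname(q$values), c(2, 5))

  gs2 <- grouped_sample(list(c(3, 2, 1), c(6, 4, 5)))
  expect_equal(pooled_quantiles(gs2, quantile_spec(0.5))$values, q$values)

  # per-group monotone in p
  set.seed(1)
  gs3 <- grouped_sample(list(rnorm(30), rnorm(25)))
  v <- pooled_quantiles(gs3, quantile_spec(c(0.25, 0.75)))$values
  expect_true(v[1] <= v[2] && v[3] <= v[4])
})

test_that("grouped_sample construction from vector + groups", {
  gs <- grouped_sample(c(1, 2, 3, 4), g = c("b", "b", "a", "b"))
  expect_equal(gs$labels, c("b", "a"))  # first-appearance order
  expect_equal(gs$sizes, c(3L, 1L))
  expect_equal(gs$n, 4L)
  expect_error(grouped_sample(c(1, NA), g = c("a", "b")), "finite")
})

test_that("rule-of-thumb bandwidth matches the 0.9 n^(-1/5) min(SD, IQR/1.34) rule", {
  # direct formula: SD = 1, IQR = 1.34 scaled sample
  set.seed(3)
  x <- rnorm(100)
  expect_equal(bandwidth_nrd(x), 0.9 * 100^(-0.2) * min(sd(x), IQR(x) / 1.34))
  # agrees with stats::bw.nrd0 on continuous data
  expect_equal(bandwidth_nrd(x), bw.nrd0(x))
  # scale equivariance
  expect_equal(bandwidth_nrd(3 * x), 3 * bandwidth_nrd(x))
  # IQR = 0 falls back to SD: 32^(-1/5) = 0.5
  y <- c(rep(0, 28), c(-4, -4, 4, 4))
  stopifnot(IQR(y) == 0)
  expect_equal(bandwidth_nrd(y), 0.9 * 32^(-0.2) * sd(y))
  # constant sample falls back to 1 with a warning
  expect_warning(b0 <- bandwidth_nrd(rep(2, 10)), "constant")
  expect_equal(b0, 0.9 * 10^(-0.2))
})

test_that("Gaussian kernel density estimate behaves like a density", {
  expect_equal(kernel_density_at(0, at = 0, bw = 1), dnorm(0))
  set.seed(11)
  x <- rnorm(5000)
  expect_equal(kernel_density_at(x, 0), 1 / sqrt(2 * pi), tolerance = 0.05)
  # translation invariance
  expect_equal(kernel_density_at(x + 10, 10, bw = 0.3),
               kernel_density_at(x, 0, bw = 0.3))
  expect_error(kernel_density_at(x, 0, bw = 0), "positive")
})

test_that("kernel covariance matches its defining formula", {
  set.seed(5)
  gs <- grouped_sample(list(rnorm(40), rnorm(60)))
  sp <- quantile_spec(c(0.25, 0.75))
  cv <- quantile_cov(gs, sp, method = "kernel")
  # recompute block 1 by hand
  x <- gs$groups[[1]]
  qh <- empirical_quantile(x, sp$p)
  f <- kernel_density_at(x, qh, bw = bandwidth_nrd(x))
  V <- outer(sp$p, sp$p, pmin) - outer(sp$p, sp$p)
  expect_equal(cv$blocks[[1]], (100 / 40) * V / outer(f, f))
  # off-diagonal numerator min - pa*pb = 0.0625 > 0
  expect_true(all(cv$blocks[[1]] > 0))
  # full matrix is the direct sum of the blocks
  expect_equal(cv$full[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(cv$full[3:4, 3:4], cv$blocks[[2]])
})

test_that("group share kappa enters covariance as 1/kappa", {
  set.seed(6)
  x <- rnorm(50)
  sp <- quantile_spec(0.5)
  solo <- quantile_cov(grouped_sample(list(x)), sp)$blocks[[1]]
  half <- quantile_cov(grouped_sample(list(x, rnorm(50))), sp)$blocks[[1]]
  expect_equal(half, 2 * solo)
})

test_that("bootstrap covariance is seeded, scaled by n, and errors on constants", {
  set.seed(8)
  gs <- grouped_sample(list(rnorm(80), rnorm(40)))
  sp <- quantile_spec(0.5)
  a <- quantile_cov(gs, sp, "bootstrap", B = 200, seed = 99)
  b <- quantile_cov(gs, sp, "bootstrap", B = 200, seed = 99)
  expect_equal(a$blocks, b$blocks)
  expect_error(
    quantile_cov(grouped_sample(list(rep(1, 30), rnorm(30))), sp,
                 "bootstrap", B = 50, seed = 1),
    "degenerate")
})

test_that("interval covariance reproduces the deterministic normal-grid oracle", {
  # sample = standard normal inverse CDF on an equispaced grid of 99 points
  x <- qnorm((1:99) / 100)
  gs <- grouped_sample(list(x))
  cv <- quantile_cov(gs, quantile_spec(0.5), "interval", gamma = 0.05)
  inv_f <- 1 / cv$density_values[1, 1]
  expect_equal(inv_f, sqrt(2 * pi), tolerance = 0.15)
  # scale equivariance: data * c scales 1/f by c, block by c^2
  cv3 <- quantile_cov(grouped_sample(list(3 * x)), quantile_spec(0.5),
                      "interval", gamma = 0.05)
  expect_equal(1 / cv3$density_values[1, 1], 3 * inv_f)
  expect_equal(cv3$blocks[[1]], 9 * cv$blocks[[1]])
  # ties break the estimator
  expect_error(
    quantile_cov(grouped_sample(list(rep(2, 5), rnorm(5))),
                 quantile_spec(0.5), "interval"),
    "tied|too small")
})

test_that("all covariance estimators are location invariant and scale c^2", {
  set.seed(12)
  x <- list(rlnorm(120), rlnorm(150))
  sp <- quantile_spec(c(0.25, 0.5, 0.75))
  for (mth in c("kernel", "interval", "bootstrap")) {
    base <- quantile_cov(grouped_sample(x), sp, mth, B = 150, seed = 21)
    shifted <- quantile_cov(grouped_sample(lapply(x, `+`, 5)), sp, mth,
                            B = 150, seed = 21)
    scaled <- quantile_cov(grouped_sample(lapply(x, `*`, 2)), sp, mth,
                           B = 150, seed = 21)
    expect_equal(shifted$blocks, base$blocks, tolerance = 1e-10,
                 label = paste(mth, "shift"))
    expect_equal(scaled$blocks, lapply(base$blocks, `*`, 4),
                 tolerance = 1e-10, label = paste(mth, "scale"))
    # blocks symmetric PSD
    for (blk in base$blocks) {
      expect_equal(blk, t(blk))
      expect_true(all(eigen(blk, symmetric = TRUE,
                            only.values = TRUE)$values > -1e-8))
    }
  }
})
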