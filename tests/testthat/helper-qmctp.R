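# shared fixtures built in code

# quantile_cov object from explicit blocks (for hand-computed oracles)
make_cov <- function(blocks) {
  blocks <- lapply(blocks, as.matrix)
  k <- length(blocks)
  m <- nrow(blocks[[1]])
  full <- matrix(0, k * m, k * m)
  for (i in seq_len(k)) {
    idx <- (i - 1L) * m + seq_len(m)
    full[idx, idx] <- blocks[[i]]
  }
  structure(list(blocks = blocks, full = full, method = "kernel",
                 density_values = NULL, settings = list(), k = k, m = m),
            class = "quantile_cov")
}

# closed-form asymptotic covariance of sqrt(n)(qhat - q) for one group
# with kappa = 1: (min(pa,pb) - pa pb) / (f(qa) f(qb))
closed_form_sigma <- function(p, qfun, dfun) {
  V <- outer(p, p, pmin) - outer(p, p)
  f <- dfun(qfun(p))
  V / outer(f, f)
}

# small deterministic grouped sample for structural tests
toy_sample <- function(k = 3, n_i = 20, seed = 42) {
  set.seed(seed)
  grouped_sample(lapply(seq_len(k), function(i) rnorm(n_i, mean = i / 2)))
}
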