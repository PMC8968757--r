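# Shared fixtures built in code.

# A random synthetic impactor trial with known truth, drawn from the
# study-shaped parameter ranges (MMAD 0.5-2 um, GSD 1.2-1.8, 5-10 mg).
random_trial <- function(seed, balance_resolution = 0.1) {
  set.seed(seed)
  m <- runif(1, 0.5, 2)
  g <- runif(1, 1.2, 1.8)
  tm <- runif(1, 5, 10)
  list(truth_mmad = m, truth_gsd = g,
       trial = simulate_impactor_trial(lognormal_psd(m, g), tm,
                                       balance_resolution = balance_resolution,
                                       seed = seed))
}

# Independent oracle for (MMAD, GSD): nonlinear least-squares fit of the
# lognormal CDF to the same cumulative undersize points the probit fit uses.
nls_cdf_oracle <- function(trial) {
  cum <- aerodose:::cumulative_undersize(trial)
  ok <- cum$fraction > 0 & cum$fraction < 1
  df <- data.frame(d = cum$d50[ok], f = cum$fraction[ok])
  fit <- minpack.lm::nlsLM(
    f ~ pnorm(log(d / mmad) / log(gsd)), data = df,
    start = list(mmad = stats::median(df$d), gsd = 1.5),
    lower = c(1e-3, 1.001), upper = c(100, 10))
  stats::coef(fit)
}

# Two-sided permutation test for a difference in group means.
permutation_p <- function(x, y, n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n <- length(x)
  stat <- replicate(n_perm, {
    idx <- sample(length(pooled), n)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
}
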