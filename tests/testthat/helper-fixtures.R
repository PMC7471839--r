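# Small synthetic fixtures shared across test files.

# a compact Table-2-calibrated cohort with missingness applied
small_cohort <- function(n = 400, seed = 2, volume_rate = 0.05,
                         morphology_rate = 0.03) {
  cohort <- generate_cohort(cohort_spec(n_subjects = n, seed = seed))
  apply_missingness(cohort, volume_rate, morphology_rate, seed = seed + 1)
}

# logistic-model simulator with known coefficients
simulate_logistic <- function(n, beta, seed) {
  set.seed(seed)
  p <- length(beta) - 1
  x <- matrix(rnorm(n * p), n, p)
  eta <- beta[1] + drop(x %*% beta[-1])
  y <- rbinom(n, 1, plogis(eta))
  list(x = cbind(1, x), y = y)
}
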