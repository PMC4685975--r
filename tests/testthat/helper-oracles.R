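# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# brute-force enumeration of monomial exponent pairs (a, b) with
# 0 <= a + b <= max_order; returns the count including the intercept
oracle_monomial_count <- function(n_vars, max_order) {
  if (n_vars == 1) {
    sum(sapply(0:max_order, function(d) 1))
  } else {
    cnt <- 0
    for (a in 0:max_order) for (b in 0:max_order) {
      if (a + b <= max_order) cnt <- cnt + 1
    }
    cnt
  }
}

# normal-equations least squares: beta = (X'X)^-1 X'y
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# literal evaluation of the published rapeseed model polynomial
oracle_model2_log <- function(iodine, rapeseed) {
  4.22 + 1.84 * iodine - 0.01 * rapeseed - 0.57 * iodine^2 +
    2.87e-05 * rapeseed^2 + 0.07 * iodine^3
}

# literal term-by-term summation of the published glucosinolate model
oracle_model1_log <- function(iodine, gsl) {
  terms <- c(4.16,
             1.89 * iodine,
             -0.152 * gsl,
             0.023 * iodine * gsl,
             -0.599 * iodine^2,
             0.0069 * gsl^2,
             -0.0016 * iodine * gsl^2,
             0.069 * iodine^3,
             -4.31e-05 * gsl^3)
  sum(terms)
}

# closed-form moments of a normal(mean, sd) truncated below at 0
oracle_truncnorm0_moments <- function(mean, sd) {
  a <- (0 - mean) / sd
  lambda <- dnorm(a) / (1 - pnorm(a))
  mu <- mean + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  c(mean = mu, sd = sqrt(v))
}

# small random treatment-mean dataset (not via the package generator)
random_dataset <- function(n, seed) {
  set.seed(seed)
  data.frame(study_id = sample(letters[1:4], n, replace = TRUE),
             iodine_in = runif(n, 0.1, 4),
             gsl = runif(n, 0, 14),
             rapeseed = runif(n, 0, 200),
             milk_iodine = exp(rnorm(n, 5, 0.5)))
}
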