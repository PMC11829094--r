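# Shared helpers: random model instances and finite-difference oracles.

# Random (Z, beta, y) instance on a Fourier design.
rand_instance <- function(seed, n = 20, p = NULL, k_max = 3) {
  set.seed(seed)
  if (is.null(p)) p <- sample(1:3, 1)
  k <- sample(0:k_max, p, replace = TRUE)
  x <- matrix(runif(n * p, 0, 2 * pi), n, p)
  Z <- fs_design(x, k)
  beta <- rnorm(ncol(Z), sd = 0.5)
  y <- rbinom(n, 1, fs_inv_logit(fs_linear_predictor(Z, beta)))
  if (all(y == y[1])) y[1] <- 1 - y[1]  # keep both classes
  list(x = x, k = k, Z = Z, beta = beta, y = y)
}

# Central finite differences of a scalar- or vector-valued function.
fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    hi <- x; lo <- x
    hi[i] <- hi[i] + h
    lo[i] <- lo[i] - h
    J[, i] <- (f(hi) - f(lo)) / (2 * h)
  }
  drop(J)
}

# Scale-aware maximum relative discrepancy.
rel_err <- function(got, ref) {
  max(abs(got - ref)) / max(1, max(abs(ref)))
}

# The canonical simulation truth used across recovery/selection tests:
# strong cosine amplitudes relative to Bernoulli noise, p = 2, K = (2, 1).
truth_beta <- function() {
  fs_coef(a0 = 0.5, b = c(0.6, -0.4), a = list(c(1.5, -1.0), 1.2))
}
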