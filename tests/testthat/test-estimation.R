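test_that("log-likelihood matches the Bernoulli pmf product", {
  Z <- fs_design(matrix(rnorm(10), 10, 1), 0)
  y <- rep(c(0, 1), 5)
  expect_equal(fs_loglik(rep(0, 2), Z, y), 10 * log(0.5))

  # term-by-term pmf product oracle on a random instance
  inst <- rand_instance(31, n = 20)
  pi_i <- fs_inv_logit(fs_linear_predictor(inst$Z, inst$beta))
  oracle <- log(prod(pi_i^inst$y * (1 - pi_i)^(1 - inst$y)))
  expect_equal(fs_loglik(inst$beta, inst$Z, inst$y), oracle)

  # y_i = 1 with eta -> +Inf contributes ~0, and no overflow occurs
  Z1 <- fs_design(cbind(x = 1), 0)
  expect_equal(fs_loglik(c(0, 700), Z1, 1), 0, tolerance = 1e-12)
  expect_error(fs_loglik(rep(0, 2), Z, c(y[-1], 2)), "coded 0/1")
})

test_that("score and Hessian have their closed forms at beta = 0", {
  n <- 24
  set.seed(32)
  Z <- fs_design(matrix(runif(n, 0, 2 * pi), n, 1), 2)
  y <- rep(c(0, 1), n / 2)
  g <- fs_score(rep(0, ncol(Z)), Z, y)
  expect_equal(g[1], 0.5 * sum(y - 0.5), ignore_attr = TRUE)
  H <- fs_hessian(rep(0, ncol(Z)), Z)
  expect_equal(H[1, 1], -n / 16)  # (1/2)^2 * 1/4 per observation

  # intercept-only model solved at pi = mean(y): intercept score is zero
  Zi <- matrix(0.5, 10, 1)
  y10 <- c(rep(1, 7), rep(0, 3))
  a0_hat <- 2 * log(0.7 / 0.3)
  expect_equal(fs_score(a0_hat, Zi, y10), 0, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("score and Hessian match finite differences; Hessian is concave", {
  for (seed in 41:45) {
    inst <- rand_instance(seed, n = 25)
    g <- fs_score(inst$beta, inst$Z, inst$y)
    g_fd <- fd_jacobian(function(b) fs_loglik(b, inst$Z, inst$y),
                        inst$beta, h = 1e-6)
    expect_lt(rel_err(g, g_fd), 1e-5)

    H <- fs_hessian(inst$beta, inst$Z)
    H_fd <- fd_jacobian(function(b) fs_score(b, inst$Z, inst$y),
                        inst$beta, h = 1e-5)
    expect_lt(rel_err(H, H_fd), 1e-4)

    expect_equal(H, t(H))
    expect_true(all(eigen(H, symmetric = TRUE,
                          only.values = TRUE)$values <= 1e-8))
  }
})

test_that("intercept-only fits hit their closed forms", {
  y <- rep(c(0, 1), 20)
  Z <- matrix(0.5, 40, 1, dimnames = list(NULL, "a0"))
  fit <- fslogit:::newton_engine(Z, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)

  y75 <- c(rep(1, 30), rep(0, 10))
  fit <- fslogit:::newton_engine(Z, y75)
  expect_equal(unname(fit$coefficients), 2 * log(3), tolerance = 1e-7)
  # deviance of the balanced null fit: 2 n ln 2
  fit0 <- fslogit:::newton_engine(Z, y)
  expect_equal(fit0$deviance, 2 * 40 * log(2), tolerance = 1e-10)
})

test_that("all-zero combo reproduces the logistic baseline after a0 = 2*b0", {
  set.seed(52)
  x <- matrix(runif(300, 0, 3), ncol = 2)
  y <- rbinom(150, 1, fs_inv_logit(0.3 + 0.5 * x[, 1] - 0.7 * x[, 2]))
  ffs <- fs_fit(x, y, k = c(0, 0))
  fbl <- fs_fit_logistic(x, y)
  expect_true(ffs$converged && fbl$converged)
  expect_lt(max(abs(ffs$coefficients -
                      c(2 * fbl$coefficients[1], fbl$coefficients[-1]))),
            1e-6)
  expect_equal(ffs$deviance, fbl$deviance, tolerance = 1e-10)
})

test_that("fit result invariants hold on a converged fit", {
  d <- fs_simulate(400, truth_beta(), seed = 53)
  fit <- fs_fit(d$x, d$y, k = c(2, 1))
  expect_true(fit$converged)
  expect_equal(fit$deviance, -2 * fit$loglik)
  expect_equal(fit$aic, fit$deviance + 2 * fit$m)
  expect_lt(fit$grad_maxnorm, 1e-5)
  expect_true(all(diff(fit$trace$loglik) >= -1e-10))  # monotone steps
  expect_true(all(eigen(-fit$neg_hessian, symmetric = TRUE,
                        only.values = TRUE)$values <= 1e-8))
  # refit from the optimum stays put
  refit <- fs_fit(d$x, d$y, k = c(2, 1), init = fit$coefficients)
  expect_lt(max(abs(refit$coefficients - fit$coefficients)), 1e-8)
  # predict on training data reproduces fitted probabilities
  expect_equal(unname(predict(fit, d$x)), unname(fit$fitted),
               tolerance = 1e-12)
})

test_that("degenerate responses are handled per contract", {
  x <- cbind(x = c(1, 2, 3, 4))
  expect_error(fs_fit_logistic(x, c(1, 1, 1, 1)), "single class")
  expect_warning(fit <- fs_fit_logistic(x, c(0, 0, 1, 1)), "separation")
  expect_false(fit$converged)
  expect_true(fit$separated)
  # too few observations: warn, not fail (may also warn about separation)
  w <- capture_warnings(fs_fit(cbind(x = c(0.3, 2.9, 4.1)), c(0, 1, 0),
                               k = 1))
  expect_match(w, "unstable", all = FALSE)
})

test_that("collinear columns produce a named singular-system error", {
  set.seed(54)
  x <- matrix(runif(60), 30, 2)
  x[, 2] <- 2 * x[, 1]  # exactly collinear linear terms
  y <- rbinom(30, 1, 0.5)
  expect_error(fs_fit(x, y, k = c(0, 0)), "offending columns")
})

test_that("AIC helper reproduces deviance + 2m", {
  expect_equal(fs_aic(0, 1), 2)
  expect_identical(fs_n_params(c(3, 2, 1, 1, 1, 1)), 16L)
  expect_identical(fs_n_params(c(4, 3, 4)), 15L)
})
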