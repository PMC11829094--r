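test_that("design matrix has the documented layout", {
  Z <- fs_design(cbind(x = c(1, 2)), k = 0)
  expect_equal(unname(Z[, ]), matrix(c(0.5, 0.5, 1, 2), 2, 2),
               ignore_attr = TRUE)

  Z <- fs_design(cbind(x = 0), k = 1)
  expect_equal(unname(Z[1, ]), c(0.5, 0, 1))  # cos(0) = 1

  Z <- fs_design(cbind(a = 1:3, b = 4:6), k = c(2, 1))
  expect_equal(colnames(Z),
               c("a0", "a", "cos(1*a)", "cos(2*a)", "b", "cos(1*b)"))
  expect_equal(Z[, "cos(2*a)"], cos(2 * (1:3)))
  tm <- attr(Z, "terms")
  expect_equal(tm$type,
               c("intercept", "linear", "cosine", "cosine",
                 "linear", "cosine"))
})

test_that("column count, bounds and intercept hold over random designs", {
  set.seed(11)
  for (rep in 1:25) {
    p <- sample(1:6, 1)
    k <- sample(0:4, p, replace = TRUE)
    n <- sample(1:40, 1)
    x <- matrix(rnorm(n * p, sd = 5), n, p)
    Z <- fs_design(x, k)
    expect_identical(ncol(Z), fs_n_params(k))
    expect_equal(unname(Z[, 1]), rep(0.5, n))
    cosc <- attr(Z, "terms")$type == "cosine"
    if (any(cosc)) {
      expect_true(all(Z[, cosc, drop = FALSE] >= -1 &
                        Z[, cosc, drop = FALSE] <= 1))
    }
  }
})

test_that("design validation names the offender", {
  x <- matrix(1, 3, 2)
  x[2, 1] <- NA
  expect_error(fs_design(x, c(1, 1)), "row 2, column 1")
  expect_error(fs_design(matrix(1, 3, 2), c(1, 1, 1)), "must equal")
  expect_error(fs_design(matrix(1, 3, 1), -1), "non-negative")
})

test_that("rescaling maps the cosine argument to [0, pi] but not the trend", {
  x <- cbind(v = c(0, 50, 100))
  Z <- fs_design(x, k = 1, rescale = TRUE)
  expect_equal(Z[, "v"], c(0, 50, 100))          # linear column raw
  expect_equal(Z[, "cos(1*v)"], cos(c(0, pi / 2, pi)))
  # explicit ranges reused on new data
  Z2 <- fs_design(cbind(v = 25), k = 1, rescale = TRUE,
                  ranges = matrix(c(0, 100), 2))
  expect_equal(Z2[, "cos(1*v)"], cos(pi / 4), ignore_attr = TRUE)
})

test_that("linear predictor matches hand arithmetic and a brute-force loop", {
  Z <- fs_design(cbind(x = 0), k = 1)
  expect_equal(fs_linear_predictor(Z, fs_coef(a0 = 2, b = 3, a = list(5))),
               0.5 * 2 + 0 + 5 * 1)
  expect_equal(fs_linear_predictor(Z, rep(0, 3)), 0)

  set.seed(21)
  Z <- fs_design(matrix(rnorm(10), 5, 2), c(1, 2))
  beta <- rnorm(ncol(Z))
  oracle <- vapply(1:5, function(i) {
    s <- 0
    for (c in seq_len(ncol(Z))) s <- s + Z[i, c] * beta[c]
    s
  }, 0)
  expect_equal(fs_linear_predictor(Z, beta), oracle)
  expect_error(fs_linear_predictor(Z, beta[-1]), "does not match")
})

test_that("inverse logit is exact, saturating and symmetric", {
  expect_equal(fs_inv_logit(0), 0.5)
  expect_equal(fs_inv_logit(log(3)), 0.75)
  hi <- fs_inv_logit(800)
  expect_true(hi < 1 && hi > 1 - 1e-12)
  lo <- fs_inv_logit(-800)
  expect_true(lo > 0 && lo < 1e-12)
  eta <- seq(-30, 30, length.out = 101)
  expect_equal(fs_inv_logit(-eta), 1 - fs_inv_logit(eta), tolerance = 1e-15)
})

test_that("coefficient blocks flatten to design order and back", {
  beta <- fs_coef(a0 = 1, b = c(2, 3), a = list(c(4, 5), numeric(0)))
  v <- as_beta_vector(beta)
  expect_equal(v, c(1, 2, 4, 5, 3))
  back <- fslogit:::split_beta(v, c(2, 0))
  expect_equal(back, beta)
  expect_error(fs_coef(1, 1:2, a = list(1)), "one vector per predictor")
})
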