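test_that("confusion metrics reproduce back-solved published-style counts", {
  # perfect predictions
  r <- fs_classify(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # class sizes 177/55 with 169 and 34 correct respectively
  y <- c(rep(0, 177), rep(1, 55))
  p_hat <- c(rep(0.2, 169), rep(0.8, 8),    # 169 of the 0s correct
             rep(0.8, 34), rep(0.2, 21))    # 34 of the 1s correct
  r <- fs_classify(y, p_hat)
  expect_equal(round(100 * r$accuracy, 2), 87.50)
  expect_equal(round(100 * r$specificity, 2), 95.48)   # class-0 rate
  expect_equal(round(100 * r$sensitivity, 2), 61.82)   # class-1 rate
  expect_equal(r$sensitivity0, r$specificity)          # orientation swap
  expect_equal(r$specificity0, r$sensitivity)
  expect_equal(r$press_q, fs_press_q(232, 203))
  expect_true(r$reject_h0)

  # class sizes 39/21 with 35 and 9 correct
  y <- c(rep(0, 39), rep(1, 21))
  p_hat <- c(rep(0, 35), rep(1, 4), rep(1, 9), rep(0, 12))
  r <- fs_classify(y, p_hat)
  expect_equal(round(100 * r$accuracy, 2), 73.33)
  expect_equal(round(100 * r$specificity, 2), 89.74)
  expect_equal(round(100 * r$sensitivity, 2), 42.86)

  # single observed class: the empty class's rate is NA, not an error
  r <- fs_classify(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(r$specificity))
  expect_true(is.na(r$auc))
  expect_error(fs_classify(c(0, 1), 0.5), "lengths differ")
  expect_error(fs_classify(c(0, 1), c(0.2, 0.8), cutoff = 1), "cutoff")
})

test_that("Mann-Whitney AUC equals pairwise concordance and ROC area", {
  expect_equal(fs_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 1)
  expect_equal(fs_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_error(fs_auc(c(1, 1), c(0.1, 0.2)), "both classes")

  set.seed(71)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    # brute-force double loop over positive-negative pairs
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
    oracle <- tot / (length(pos) * length(neg))
    expect_equal(fs_auc(y, s), oracle)

    # alternative construction: trapezoidal area under the empirical ROC
    th <- sort(unique(s), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(s[y == 1] >= t), 0))
    fpr <- c(0, vapply(th, function(t) mean(s[y == 0] >= t), 0))
    area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    expect_equal(fs_auc(y, s), area)
  }
})

test_that("Press's Q formula, invariances and errors", {
  expect_equal(fs_press_q(232, 203), 130.5)
  expect_equal(fs_press_q(60, 44), 784 / 60)
  # all correct: Q = n for k = 2
  expect_equal(fs_press_q(57, 57), 57)
  # relabeling classes keeps n_correct, hence Q
  expect_equal(fs_press_q(100, 80), fs_press_q(100, 80, 2))
  # exactly chance-level correct count gives 0
  expect_equal(fs_press_q(100, 50), 0)
  expect_error(fs_press_q(0, 0), "positive")
  expect_error(fs_press_q(10, 11), "n_correct")
  expect_error(fs_press_q(10, 5, 1), "k_groups")
})

test_that("chi-square threshold matches the normal-quantile identity", {
  # independent route at df = 1: chi2 quantile = (z_{1-alpha/2})^2
  for (alpha in c(0.05, 0.5, 0.2)) {
    expect_equal(fs_chisq_crit(alpha, 1), stats::qnorm(1 - alpha / 2)^2,
                 tolerance = 1e-12)
  }
  expect_lt(fs_chisq_crit(0.999, 1), 1e-4)  # alpha -> 1 limit
  expect_error(fs_chisq_crit(1.2), "alpha")
  expect_error(fs_chisq_crit(0.05, 0), "df")
})

test_that("model comparison flags the winners and ties", {
  d <- fs_simulate(500, fs_coef(0.2, c(0, 0.3), a = list(c(1.8, -1.2), 0)),
                   seed = 4)
  ffs <- fs_fit(d$x, d$y, k = c(2, 0))
  fbl <- fs_fit_logistic(d$x, d$y)
  cmp <- fs_compare(list(fourier = ffs, logistic = fbl), d$y)
  expect_equal(cmp$best_deviance, "fourier")
  expect_lt(ffs$deviance, fbl$deviance)
  expect_false(cmp$tie_deviance)

  tie <- fs_compare(list(a = ffs, b = ffs), d$y)
  expect_true(tie$tie_deviance)
  expect_equal(tie$table$deviance[1], tie$table$deviance[2])

  one <- fs_compare(list(only = fbl), d$y)
  expect_equal(one$best_deviance, "only")
  expect_error(fs_compare(list(), d$y), "non-empty")
})

test_that("grouped proportions bin correctly and track the true curve", {
  g <- fs_grouped_proportions(c(1, 1, 2, 2), c(0, 1, 0, 1), 2)
  expect_equal(g$proportion, c(0.5, 0.5))
  expect_equal(g$count, c(2, 2))

  g <- fs_grouped_proportions(1:8, rep(1, 8), 4)
  expect_true(all(g$proportion == 1))

  expect_warning(g <- fs_grouped_proportions(rep(2, 5), rep(0:1, c(2, 3)), 3),
                 "single bin")
  expect_equal(nrow(g), 1L)
  expect_equal(g$count, 5)

  # empty interior bin reported with count 0 and NA proportion
  g <- fs_grouped_proportions(c(0, 0.1, 2.9, 3), c(0, 0, 1, 1), 3)
  expect_equal(g$count[2], 0)
  expect_true(is.na(g$proportion[2]))

  # binned proportions follow a cosine-shaped truth
  d <- fs_simulate(1000, fs_coef(0, 0, a = list(2.0)), seed = 72)
  g <- fs_grouped_proportions(d$x[, 1], d$y, 12)
  truth <- fs_inv_logit(2.0 * cos(g$midpoint))
  expect_gt(stats::cor(g$proportion, truth, use = "complete.obs"), 0.9)
})
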