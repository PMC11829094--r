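#' Confusion-matrix classification metrics
#'
#' Classifies observation i as 1 when `p_hat[i] >= cutoff` and tabulates
#' the 2 x 2 confusion matrix, overall accuracy, and sensitivity /
#' specificity under both labelings of "positive". Application datasets in
#' this field are inconsistent about which class is the event, so both
#' orientations are always reported: `sensitivity` / `specificity` treat
#' class 1 as positive; `sensitivity0` / `specificity0` treat class 0 as
#' positive (the two pairs are mutual swaps). A class absent from `y`
#' yields `NA` rates rather than an error.
#'
#' Also attaches the Mann-Whitney AUC, Press's Q and its chi-square
#' threshold, so one call produces a full classification report.
#'
#' @param y observed binary response (0/1).
#' @param p_hat fitted probabilities, same length.
#' @param cutoff classification threshold in (0, 1), default 0.5.
#' @param alpha significance level for the Press's Q threshold.
#' @return object of class `"fs_classification"`: list with `n`, `counts`
#'   (2 x 2 matrix, rows = observed, cols = predicted), `accuracy`,
#'   `sensitivity`, `specificity`, `sensitivity0`, `specificity0`, `auc`
#'   (NA if single-class), `press_q`, `chi2_crit`, `reject_h0`, `cutoff`.
#' @export
fs_classify <- function(y, p_hat, cutoff = 0.5, alpha = 0.05) {
  y <- check_binary(y)
  p_hat <- as.numeric(p_hat)
  if (length(p_hat) != length(y)) {
    stop("`y` and `p_hat` lengths differ", call. = FALSE)
  }
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("`cutoff` must be strictly inside (0, 1)", call. = FALSE)
  }
  pred <- as.numeric(p_hat >= cutoff)
  counts <- table(factor(y, levels = c(0, 1)),
                  factor(pred, levels = c(0, 1)))
  counts <- matrix(as.numeric(counts), 2, 2,
                   dimnames = list(observed = c("0", "1"),
                                   predicted = c("0", "1")))
  n <- length(y)
  n1 <- sum(y == 1); n0 <- n - n1
  correct <- counts["0", "0"] + counts["1", "1"]
  sens1 <- if (n1 > 0) counts["1", "1"] / n1 else NA_real_
  spec1 <- if (n0 > 0) counts["0", "0"] / n0 else NA_real_
  auc <- if (n1 > 0 && n0 > 0) fs_auc(y, p_hat) else NA_real_
  q <- fs_press_q(n, correct)
  crit <- fs_chisq_crit(alpha = alpha, df = 1L)
  structure(list(n = n, counts = counts,
                 n_correct = correct,
                 accuracy = correct / n,
                 sensitivity = sens1, specificity = spec1,
                 sensitivity0 = spec1, specificity0 = sens1,
                 auc = auc,
                 press_q = q, chi2_crit = crit,
                 reject_h0 = q > crit,
                 cutoff = cutoff, alpha = alpha),
            class = "fs_classification")
}

#' @export
print.fs_classification <- function(x, ...) {
  cat("Classification at cutoff ", x$cutoff, " (n = ", x$n, ")\n", sep = "")
  print(x$counts)
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat("accuracy ", pc(x$accuracy),
      " | sens/spec (1 positive) ", pc(x$sensitivity), "/",
      pc(x$specificity),
      " | AUC ", pc(x$auc), "\n", sep = "")
  cat("Press's Q = ", sprintf("%.4f", x$press_q),
      " vs chi-square(", x$alpha, ", 1) = ",
      sprintf("%.4f", x$chi2_crit),
      if (x$reject_h0) "  => classification beats chance" else "", "\n",
      sep = "")
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen positive (y = 1) receives a higher
#' score than a randomly chosen negative, with ties counted 1/2 — the
#' rank-sum formulation of the area under the ROC curve.
#'
#' @param y binary response (0/1), both classes present.
#' @param p_hat scores (typically fitted probabilities).
#' @return AUC in \[0, 1\].
#' @export
fs_auc <- function(y, p_hat) {
  y <- check_binary(y)
  if (length(p_hat) != length(y)) {
    stop("`y` and `p_hat` lengths differ", call. = FALSE)
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(p_hat)  # midranks handle ties at 1/2 per tied pair
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Press's Q statistic
#'
#' \deqn{Q = \frac{(n - n_{correct} \cdot k)^2}{n (k - 1)}}
#' for `k` groups; referred to a chi-square distribution with k - 1 degrees
#' of freedom to test whether classification accuracy beats chance.
#'
#' @param n total number of classified observations (> 0).
#' @param n_correct number correctly classified, `0 <= n_correct <= n`.
#' @param k_groups number of groups (default 2).
#' @return scalar Q >= 0.
#' @examples
#' fs_press_q(232, 203)  # 130.5
#' @export
fs_press_q <- function(n, n_correct, k_groups = 2L) {
  if (length(n) != 1L || n <= 0) stop("`n` must be positive", call. = FALSE)
  if (n_correct < 0 || n_correct > n) {
    stop("`n_correct` must lie in [0, n]", call. = FALSE)
  }
  if (k_groups < 2L) stop("`k_groups` must be >= 2", call. = FALSE)
  (n - n_correct * k_groups)^2 / (n * (k_groups - 1))
}

#' Chi-square critical value
#'
#' Upper (1 - alpha) quantile of the chi-square distribution, the threshold
#' Press's Q is compared against (df = k_groups - 1).
#'
#' @param alpha significance level in (0, 1), default 0.05.
#' @param df degrees of freedom, default 1.
#' @export
fs_chisq_crit <- function(alpha = 0.05, df = 1L) {
  if (!(alpha > 0 && alpha < 1)) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (df < 1L) stop("`df` must be >= 1", call. = FALSE)
  stats::qchisq(1 - alpha, df = df)
}

#' Compare fitted models on one response
#'
#' Tabulates deviance, AIC and the full classification report for each fit
#' and flags the smallest-deviance and largest-AUC models. All fits must be
#' on the same response vector.
#'
#' @param fits named list of `fs_fit` objects.
#' @param y binary response all fits were trained on.
#' @param cutoff classification threshold, default 0.5.
#' @return object of class `"fs_comparison"`: data frame `table` with one
#'   row per model plus attributes `best_deviance`, `best_auc`, and
#'   `reports` (the per-model `fs_classification` objects).
#' @export
fs_compare <- function(fits, y, cutoff = 0.5) {
  if (!length(fits)) stop("`fits` must be non-empty", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  y <- check_binary(y)
  reports <- lapply(fits, function(f) fs_classify(y, f$fitted, cutoff))
  tab <- do.call(rbind, Map(function(nm, f, r) {
    data.frame(model = nm, m = f$m,
               deviance = f$deviance, aic = f$aic,
               accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               auc = r$auc, press_q = r$press_q,
               reject_h0 = r$reject_h0,
               converged = f$converged,
               stringsAsFactors = FALSE)
  }, names(fits), fits, reports))
  rownames(tab) <- NULL
  dev_best <- tab$model[tab$deviance <= min(tab$deviance) + 1e-12]
  auc_best <- tab$model[!is.na(tab$auc) &
                          tab$auc >= max(tab$auc, na.rm = TRUE) - 1e-12]
  structure(list(table = tab,
                 best_deviance = dev_best, best_auc = auc_best,
                 tie_deviance = length(dev_best) > 1L,
                 reports = reports, cutoff = cutoff),
            class = "fs_comparison")
}

#' @export
print.fs_comparison <- function(x, ...) {
  tab <- x$table
  tab$deviance <- round(tab$deviance, 4)
  tab$aic <- round(tab$aic, 4)
  for (cc in c("accuracy", "sensitivity", "specificity", "auc")) {
    tab[[cc]] <- sprintf("%.2f%%", 100 * tab[[cc]])
  }
  tab$press_q <- round(tab$press_q, 4)
  print(tab, row.names = FALSE)
  cat("smallest deviance: ", paste(x$best_deviance, collapse = ", "),
      if (x$tie_deviance) " (tie)", "\n", sep = "")
  cat("largest AUC: ", paste(x$best_auc, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Grouped empirical proportions for pattern diagnostics
#'
#' Bins a predictor into `n_bins` equal-width intervals and reports, per
#' bin, the midpoint, the empirical proportion of successes and the count —
#' the scatterplot diagnostic used to spot a repeating (cosine-like)
#' relationship between a predictor and the event probability. Empty bins
#' are emitted with count 0 and proportion NA.
#'
#' @param x numeric predictor vector.
#' @param y binary response (0/1).
#' @param n_bins number of equal-width bins (>= 1).
#' @return data frame with columns `midpoint`, `proportion`, `count`.
#' @export
fs_grouped_proportions <- function(x, y, n_bins) {
  y <- check_binary(y)
  x <- as.numeric(x)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2] && n_bins > 1L) {
    warning("constant `x`: falling back to a single bin", call. = FALSE)
    n_bins <- 1L
  }
  if (n_bins == 1L) {
    return(data.frame(midpoint = mean(rng), proportion = mean(y),
                      count = length(y)))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  cnt <- tabulate(idx, nbins = n_bins)
  prop <- vapply(seq_len(n_bins), function(b) {
    if (cnt[b] == 0L) NA_real_ else mean(y[idx == b])
  }, 0)
  data.frame(midpoint = mids, proportion = prop, count = cnt)
}
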