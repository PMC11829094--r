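#' Enumerate oscillation-parameter combinations
#'
#' All vectors \eqn{(K_1, \dots, K_p)} with each component in
#' `k_min:k_max`, in deterministic lexicographic order (last component
#' varies fastest).
#'
#' @param p number of predictors.
#' @param k_max largest harmonic count per predictor.
#' @param k_min smallest (default 1; during selection no predictor is
#'   reduced to purely linear, but `k_min = 0` combos remain constructible).
#' @return list of integer vectors of length p.
#' @examples
#' fs_combos(1, 2)          # (1), (2)
#' length(fs_combos(3, 4))  # 64
#' @export
fs_combos <- function(p, k_max, k_min = 1L) {
  p <- as.integer(p); k_max <- as.integer(k_max); k_min <- as.integer(k_min)
  if (p < 1L) stop("`p` must be >= 1", call. = FALSE)
  if (k_min < 0L || k_max < k_min) {
    stop("need 0 <= k_min <= k_max", call. = FALSE)
  }
  vals <- k_min:k_max
  grid <- do.call(expand.grid, rev(rep(list(vals), p)))
  grid <- as.matrix(grid)[, rev(seq_len(p)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

#' Minimum-AIC search over oscillation-parameter combinations
#'
#' Fits the cosine-series logit model for every combination in
#' \eqn{\{k_{min}, \dots, k_{max}\}^p} (exhaustive grid, the default) and
#' selects the global minimum-AIC model. For each level
#' \eqn{K = k_{min}, \dots, k_{max}} the cumulative minimum — the best AIC
#' among combos whose largest component is at most K — is also reported, so
#' a level whose extra harmonics never help repeats the previous row.
#'
#' Ties in AIC are broken by smaller \eqn{\sum_j K_j}, then lexicographic
#' order. Non-converged fits are excluded from selection with a warning.
#'
#' For large p the exhaustive grid grows as \eqn{(k_{max})^p}; the
#' `"greedy"` mode instead increments one predictor's K per step, keeping
#' the move with the best AIC until no move improves. Greedy search is a
#' heuristic and can miss the global minimum.
#'
#' @param x predictor matrix (n x p).
#' @param y binary response coded 0/1.
#' @param k_max largest harmonic count searched (default 4).
#' @param k_min smallest (default 1).
#' @param method `"grid"` (exhaustive, default) or `"greedy"`.
#' @param rescale,ranges,eps,max_iter passed to [fs_fit()].
#' @return An object of class `"fs_selection"`: list with `table` (one row
#'   per fitted combo: combo string, level = max K_j, sum_k, aic, deviance,
#'   converged), `levels` (per-level cumulative minimum AIC and its combo),
#'   `best_combo`, `best_aic`, `best_fit` (the refitted winner), `method`.
#' @examples
#' set.seed(42)
#' x <- matrix(runif(600, 0, 2 * pi), ncol = 2)
#' eta <- 1.5 * cos(x[, 1]) + 0.3 * x[, 2]
#' y <- rbinom(300, 1, fs_inv_logit(eta))
#' sel <- fs_select(x, y, k_max = 2)
#' sel$best_combo
#' @export
fs_select <- function(x, y, k_max = 4L, k_min = 1L,
                      method = c("grid", "greedy"),
                      rescale = FALSE, ranges = NULL,
                      eps = 1e-6, max_iter = 100L) {
  method <- match.arg(method)
  x <- as_predictor_matrix(x)
  p <- ncol(x)
  if (k_max < 1L) stop("`k_max` must be >= 1", call. = FALSE)

  fit_one <- function(k) {
    fit <- withCallingHandlers(
      fs_fit(x, y, k = k, rescale = rescale, ranges = ranges,
             eps = eps, max_iter = max_iter),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(combo = paste(k, collapse = ","),
               level = max(k), sum_k = sum(k),
               m = fit$m, deviance = fit$deviance, aic = fit$aic,
               converged = fit$converged, stringsAsFactors = FALSE)
  }

  if (method == "grid") {
    combos <- fs_combos(p, k_max, k_min)
    tab <- do.call(rbind, lapply(combos, fit_one))
  } else {
    combos <- list(); tab <- NULL
    cur <- rep(k_min, p)
    row <- fit_one(cur); combos <- list(cur); tab <- row
    repeat {
      best_aic <- min(tab$aic[tab$converged], Inf)
      moves <- lapply(seq_len(p), function(j) {
        kk <- cur; kk[j] <- kk[j] + 1L; kk
      })
      moves <- Filter(function(kk) max(kk) <= k_max, moves)
      if (!length(moves)) break
      rows <- lapply(moves, fit_one)
      aics <- vapply(rows, function(r) ifelse(r$converged, r$aic, Inf), 0)
      combos <- c(combos, moves)
      tab <- rbind(tab, do.call(rbind, rows))
      if (min(aics) >= best_aic) break
      cur <- moves[[which.min(aics)]]
    }
  }

  ok <- tab$converged
  if (!any(ok)) {
    stop("no oscillation-parameter combination produced a converged fit",
         call. = FALSE)
  }
  if (any(!ok)) {
    warning(sum(!ok), " combination(s) excluded for non-convergence: ",
            paste(tab$combo[!ok], collapse = "; "), call. = FALSE)
  }

  pick <- function(rows) {
    # min AIC; ties by smaller sum of K, then lexicographic combo order
    rows <- rows[order(rows$aic, rows$sum_k, rows$combo), , drop = FALSE]
    rows[1L, , drop = FALSE]
  }
  best_row <- pick(tab[ok, , drop = FALSE])

  lev_ids <- sort(unique(tab$level))
  levels <- do.call(rbind, lapply(lev_ids, function(L) {
    sub <- tab[ok & tab$level <= L, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    w <- pick(sub)
    data.frame(level = L, combo = w$combo, aic = w$aic,
               stringsAsFactors = FALSE)
  }))

  best_combo <- as.integer(strsplit(best_row$combo, ",")[[1L]])
  best_fit <- fs_fit(x, y, k = best_combo, rescale = rescale,
                     ranges = ranges, eps = eps, max_iter = max_iter)

  structure(list(table = tab, levels = levels,
                 best_combo = best_combo, best_aic = best_row$aic,
                 best_fit = best_fit, method = method,
                 k_max = as.integer(k_max), k_min = as.integer(k_min)),
            class = "fs_selection")
}

#' @export
print.fs_selection <- function(x, ...) {
  cat("Oscillation-parameter selection (", x$method, " search, K in ",
      x$k_min, "..", x$k_max, ")\n", sep = "")
  cat("Per-level cumulative minimum AIC:\n")
  print(x$levels, row.names = FALSE)
  cat("Best combination: (", paste(x$best_combo, collapse = ","),
      ")  AIC = ", format(x$best_aic, digits = 8), "\n", sep = "")
  invisible(x)
}
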