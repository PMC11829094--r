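#' Bernoulli log-likelihood of the cosine-series logit model
#'
#' \eqn{L(\beta) = \sum_i \{ y_i \eta_i - \ln(1 + e^{\eta_i}) \}} with
#' \eqn{\eta = Z\beta}, the numerically stable form of
#' \eqn{\sum y_i \ln \pi_i + \sum (1 - y_i)\ln(1 - \pi_i)}.
#'
#' @param beta coefficient vector or [fs_coef] aligned with `Z`.
#' @param Z design matrix ([fs_design()]).
#' @param y binary response vector coded 0/1.
#' @return scalar log-likelihood.
#' @export
fs_loglik <- function(beta, Z, y) {
  y <- check_binary(y, nrow(Z))
  eta <- fs_linear_predictor(Z, beta)
  sum(y * eta - log1p_exp(eta))
}

# log(1 + exp(eta)) without overflow: for large eta, = eta + log1p(exp(-eta)).
log1p_exp <- function(eta) {
  out <- numeric(length(eta))
  hi <- eta > 30
  out[hi] <- eta[hi] + log1p(exp(-eta[hi]))
  out[!hi] <- log1p(exp(eta[!hi]))
  out
}

check_binary <- function(y, n = NULL) {
  y <- as.numeric(y)
  if (!is.null(n) && length(y) != n) {
    stop("response length ", length(y), " does not match ", n, " rows",
         call. = FALSE)
  }
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    bad <- which(is.na(y) | !(y %in% c(0, 1)))
    stop("response must be coded 0/1; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  y
}

#' Score vector (gradient of the log-likelihood)
#'
#' \eqn{g(\beta) = Z^\top (y - \pi)}. Component-wise this reproduces the
#' estimating equations of the model: \eqn{\sum_i (y_i - \pi_i) x_{ji}} for
#' the linear terms, \eqn{\sum_i \frac{1}{2}(y_i - \pi_i)} for the
#' 1/2-intercept, and \eqn{\sum_i \cos(k x_{ji}) (y_i - \pi_i)} for each
#' harmonic.
#'
#' @inheritParams fs_loglik
#' @return numeric vector of length `ncol(Z)`.
#' @export
fs_score <- function(beta, Z, y) {
  y <- check_binary(y, nrow(Z))
  pi_hat <- fs_inv_logit(fs_linear_predictor(Z, beta))
  drop(crossprod(Z, y - pi_hat))
}

#' Hessian of the log-likelihood
#'
#' \eqn{H(\beta) = -Z^\top W Z} with \eqn{W = diag(\pi_i (1 - \pi_i))}.
#' The 1/2-intercept column makes the intercept-intercept entry
#' \eqn{-\frac{1}{4}\sum \pi_i(1-\pi_i)} and the intercept-by-other entries
#' carry the 1/2 factor. Symmetric and negative semidefinite everywhere
#' (canonical-link concavity).
#'
#' @inheritParams fs_loglik
#' @return m x m matrix, m = `ncol(Z)`.
#' @export
fs_hessian <- function(beta, Z) {
  pi_hat <- fs_inv_logit(fs_linear_predictor(Z, beta))
  w <- pi_hat * (1 - pi_hat)
  -crossprod(Z, Z * w)
}

#' Fit the cosine-series logit model by Newton-Raphson
#'
#' Maximum-likelihood fit of the model
#' \deqn{\mathrm{logit}\,\pi_i = \tfrac{1}{2}a_0 + \sum_{j=1}^p \Big( b_j
#'   x_{ji} + \sum_{k=1}^{K_j} a_{kj} \cos(k x_{ji}) \Big)}
#' by Newton-Raphson iteration
#' \eqn{\beta^{(t+1)} = \beta^{(t)} - H^{-1} g}, starting from
#' \eqn{\beta^{(0)} = 0} (or `init`), with step-halving whenever the full
#' step would decrease the log-likelihood. Iteration stops when the
#' max-norm coefficient change falls below `eps` or after `max_iter`
#' iterations.
#'
#' A numerically singular Hessian is retried once with a ridge of
#' `1e-8` on the diagonal; if still singular the fit fails with an error
#' naming the offending (collinear) columns. Separation — any coefficient
#' exceeding 1e3 in magnitude, or fitted probabilities within 1e-10 of 0/1
#' while the gradient norm is no longer decreasing — yields a warning and
#' `converged = FALSE`, not an error.
#'
#' @param x predictor matrix (n x p) or an existing [fs_design()] matrix.
#' @param y binary response coded 0/1, with both classes present.
#' @param k oscillation-parameter vector (ignored when `x` is already a
#'   design matrix). Default all zeros (no cosine terms).
#' @param rescale,ranges passed to [fs_design()].
#' @param init optional starting coefficient vector (default zeros).
#' @param eps convergence threshold on the max-norm coefficient change
#'   (default `1e-6`).
#' @param max_iter maximum Newton iterations (default 100).
#' @return An object of class `"fs_fit"` with components `coefficients`
#'   (named vector), `beta` (structured [fs_coef], Fourier designs only),
#'   `loglik`, `deviance` (\eqn{-2 \log L}; the saturated log-likelihood of
#'   ungrouped binary data is 0), `aic` (\eqn{-2\log L + 2m}), `n_iter`,
#'   `converged`, `grad_maxnorm`, `neg_hessian` (observed information at the
#'   optimum), `fitted` (probabilities), `trace` (per-iteration
#'   log-likelihood, max coefficient change, step halvings), `n`, `m`,
#'   `combo`, `design` attributes for prediction.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(400, 0, 2 * pi), ncol = 2)
#' eta <- 0.5 * x[, 1] + 1.2 * cos(x[, 2])
#' y <- rbinom(200, 1, fs_inv_logit(eta))
#' fit <- fs_fit(x, y, k = c(0, 1))
#' coef(fit)
#' @export
fs_fit <- function(x, y, k = NULL, rescale = FALSE, ranges = NULL,
                   init = NULL, eps = 1e-6, max_iter = 100L) {
  if (inherits(x, "fs_design")) {
    Z <- x
  } else {
    x <- as_predictor_matrix(x)
    if (is.null(k)) k <- rep(0L, ncol(x))
    Z <- fs_design(x, k, rescale = rescale, ranges = ranges)
  }
  res <- newton_engine(Z, y, init = init, eps = eps, max_iter = max_iter)
  res$combo <- attr(Z, "combo")
  res$beta <- split_beta(res$coefficients, res$combo)
  res$model <- "fourier"
  res$design_attrs <- list(rescale = attr(Z, "rescale"),
                           ranges = attr(Z, "ranges"),
                           predictors = attr(Z, "predictors"))
  res
}

#' Fit the binary-logistic baseline
#'
#' Plain logistic regression \eqn{\mathrm{logit}\,\pi_i = \beta_0 + \sum_l
#' \beta_l x_{li}} — an intercept on a constant-1 column plus linear terms —
#' fitted by the same Newton-Raphson engine as [fs_fit()]. Equivalent to a
#' Fourier fit with all oscillation parameters zero, up to the intercept
#' reparameterization \eqn{a_0 = 2\beta_0}.
#'
#' @inheritParams fs_fit
#' @return `"fs_fit"` object with `model = "logistic"`; `coefficients` are
#'   `(Intercept)`, then one slope per predictor.
#' @export
fs_fit_logistic <- function(x, y, init = NULL, eps = 1e-6, max_iter = 100L) {
  x <- as_predictor_matrix(x)
  Z <- cbind("(Intercept)" = 1, x)
  res <- newton_engine(Z, y, init = init, eps = eps, max_iter = max_iter)
  res$combo <- NULL
  res$model <- "logistic"
  res$design_attrs <- list(rescale = FALSE, ranges = NULL,
                           predictors = colnames(x))
  res
}

# Core Newton-Raphson maximiser shared by both fitters. Z is any numeric
# design matrix; y is 0/1. Monotone in the log-likelihood via step-halving.
newton_engine <- function(Z, y, init = NULL, eps = 1e-6, max_iter = 100L) {
  y <- check_binary(y, nrow(Z))
  n <- nrow(Z); m <- ncol(Z)
  if (all(y == 1) || all(y == 0)) {
    stop("response has a single class; the MLE does not exist (separation)",
         call. = FALSE)
  }
  if (n <= m) {
    warning("n (", n, ") <= number of parameters (", m,
            "); fit may be unstable", call. = FALSE)
  }
  beta <- if (is.null(init)) numeric(m) else as_beta_vector(init)
  if (length(beta) != m) {
    stop("`init` length ", length(beta), " does not match ", m,
         " design columns", call. = FALSE)
  }

  ll <- fs_loglik(beta, Z, y)
  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      max_change = numeric(0), halvings = integer(0))
  converged <- FALSE
  separated <- FALSE
  ridge_used <- FALSE
  prev_gnorm <- Inf
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    g <- fs_score(beta, Z, y)
    H <- fs_hessian(beta, Z)
    sv <- solve_newton_step(H, g, Z, ridge_used)
    step <- sv$step
    ridge_used <- ridge_used || sv$ridged

    # step-halving: accept the largest step (<= full Newton) that does not
    # decrease the log-likelihood
    lambda <- 1
    halv <- 0L
    repeat {
      cand <- beta + lambda * step
      ll_cand <- fs_loglik(cand, Z, y)
      if (is.finite(ll_cand) && ll_cand >= ll) break
      halv <- halv + 1L
      if (halv > 30L) break
      lambda <- lambda / 2
    }
    if (halv > 30L) break  # no improving step found: at a numerical optimum

    delta <- max(abs(cand - beta))
    beta <- cand
    ll <- ll_cand
    trace <- rbind(trace, data.frame(iter = it, loglik = ll,
                                     max_change = delta, halvings = halv))

    gnorm <- max(abs(fs_score(beta, Z, y)))
    pfit <- fs_inv_logit(fs_linear_predictor(Z, beta))
    if (max(abs(beta)) > 1e3 ||
        (any(pmin(pfit, 1 - pfit) < 1e-10) && gnorm >= prev_gnorm)) {
      separated <- TRUE
      break
    }
    prev_gnorm <- gnorm

    if (delta < eps) {
      converged <- TRUE
      break
    }
  }

  if (separated) {
    warning("possible complete or quasi-complete separation detected; ",
            "coefficients diverging, fit marked non-converged",
            call. = FALSE)
    converged <- FALSE
  }

  g <- fs_score(beta, Z, y)
  H <- fs_hessian(beta, Z)
  names(beta) <- colnames(Z)
  structure(list(
    coefficients = beta,
    loglik = ll,
    deviance = -2 * ll,
    aic = -2 * ll + 2 * m,
    n_iter = it,
    converged = converged,
    separated = separated,
    grad_maxnorm = max(abs(g)),
    neg_hessian = -H,
    fitted = fs_inv_logit(fs_linear_predictor(Z, beta)),
    trace = trace,
    n = n, m = m,
    y = y
  ), class = "fs_fit")
}

# Solve H step = -g (i.e. step = -H^{-1} g). A single ridge rescue of
# 1e-8 I is allowed for transient ill-conditioning; a Hessian that is
# singular again afterwards signals genuinely collinear columns, and we
# fail naming them rather than let a pseudo-inverse hide the problem.
solve_newton_step <- function(H, g, Z, ridge_used) {
  st <- tryCatch(solve(H, -g), error = function(e) NULL)
  if (!is.null(st) && all(is.finite(st))) {
    return(list(step = drop(st), ridged = FALSE))
  }
  if (!ridge_used) {
    Hr <- H - 1e-8 * diag(nrow(H))
    st <- tryCatch(solve(Hr, -g), error = function(e) NULL)
    if (!is.null(st) && all(is.finite(st))) {
      return(list(step = drop(st), ridged = TRUE))
    }
  }
  qz <- qr(Z)
  bad <- if (qz$rank < ncol(Z)) {
    colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
  } else "<unidentified>"
  stop("Hessian numerically singular", if (ridge_used)
       " (ridge fallback already used)" else " even after ridge fallback",
       "; offending columns: ", paste(bad, collapse = ", "),
       call. = FALSE)
}

#' @export
print.fs_fit <- function(x, ...) {
  cat(if (identical(x$model, "logistic")) "Binary logistic fit"
      else paste0("Fourier-series logit fit (K = ",
                  paste(x$combo, collapse = ","), ")"),
      "\n", sep = "")
  cat("  n = ", x$n, ", parameters = ", x$m,
      ", iterations = ", x$n_iter,
      ", converged: ", x$converged, "\n", sep = "")
  cat("  logLik = ", format(x$loglik, digits = 7),
      ", deviance = ", format(x$deviance, digits = 7),
      ", AIC = ", format(x$aic, digits = 7), "\n", sep = "")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.fs_fit <- function(object, ...) object$coefficients

#' @export
logLik.fs_fit <- function(object, ...) {
  structure(object$loglik, df = object$m, nobs = object$n, class = "logLik")
}

#' Deviance of a fit
#'
#' For ungrouped binary data the saturated log-likelihood is 0, so the
#' deviance is \eqn{-2 \log L}.
#'
#' @param object an `fs_fit`.
#' @param ... unused.
#' @return scalar deviance.
#' @export
deviance.fs_fit <- function(object, ...) object$deviance

#' AIC helper on the deviance scale
#'
#' \eqn{AIC = deviance + 2m} with \eqn{m = 1 + p + \sum_j K_j}. Exposed so
#' printed deviance/parameter-count pairs can be cross-checked without a
#' fitted object.
#'
#' @param deviance model deviance (\eqn{-2\log L}).
#' @param m number of parameters, e.g. [fs_n_params()].
#' @return scalar AIC.
#' @examples
#' fs_aic(24.0027, fs_n_params(c(4, 3, 4)))  # 54.0027
#' @export
fs_aic <- function(deviance, m) deviance + 2 * m

#' Predicted probabilities for new data
#'
#' @param object an `fs_fit`.
#' @param newdata predictor matrix/data frame; omitted returns fitted values.
#' @param type `"response"` (probability) or `"link"` (logit scale).
#' @param ... unused.
#' @export
predict.fs_fit <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    return(stats::qlogis(object$fitted))
  }
  x <- as_predictor_matrix(newdata)
  Z <- if (identical(object$model, "logistic")) {
    cbind("(Intercept)" = 1, x)
  } else {
    da <- object$design_attrs
    fs_design(x, object$combo, rescale = da$rescale, ranges = da$ranges)
  }
  eta <- fs_linear_predictor(Z, object$coefficients)
  if (type == "response") fs_inv_logit(eta) else eta
}
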