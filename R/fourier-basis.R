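#' Build the Fourier-series design matrix
#'
#' Expands a matrix of continuous predictors into the design matrix of the
#' cosine-series logit model. Each predictor \eqn{x_j} contributes a linear
#' column \eqn{x_j} and \eqn{K_j} cosine columns \eqn{\cos(k x_j)},
#' \eqn{k = 1, \dots, K_j}; a single shared intercept column with constant
#' value 1/2 comes first. The 1/2 scaling keeps the reported intercept on
#' the same parameterization as the model's logit
#' \eqn{\frac{1}{2}a_0 + \sum_j (b_j x_j + \sum_k a_{kj} \cos(k x_j))}.
#'
#' Column order is fixed: intercept, then for each predictor j its linear
#' column followed by its cosine columns in increasing k. The total number
#' of columns is \eqn{m = 1 + p + \sum_j K_j}.
#'
#' By default predictors enter `cos(k*x)` in their native units. With
#' `rescale = TRUE` each predictor is affinely mapped to \eqn{[0, \pi]}
#' before the cosine (only; the linear column keeps raw values), which slows
#' the oscillation for wide-range predictors such as percentages. The map is
#' taken from `ranges` when supplied (a 2-row matrix of per-predictor
#' low/high), otherwise from the observed min/max, and is stored on the
#' result so new data can be expanded consistently.
#'
#' @param x numeric matrix or data frame, n rows by p predictors; all
#'   entries must be finite.
#' @param k integer vector of length p: the oscillation parameter
#'   \eqn{K_j \ge 0} per predictor. A single value is recycled.
#' @param rescale logical; map predictors to \eqn{[0, \pi]} inside the
#'   cosine terms. Default `FALSE`.
#' @param ranges optional 2 x p matrix of (low, high) used for rescaling.
#' @return An object of class `"fs_design"`: the n x m numeric matrix with
#'   attributes `combo` (the K vector), `terms` (a data frame describing
#'   each column: type, predictor index, harmonic), `predictors` (names),
#'   `rescale`, `ranges`.
#' @examples
#' Z <- fs_design(cbind(x = c(1, 2)), k = 0)
#' Z                       # columns: 1/2-intercept, x
#' fs_design(cbind(x = 0), k = 1)   # cos(0) = 1
#' @export
fs_design <- function(x, k, rescale = FALSE, ranges = NULL) {
  x <- as_predictor_matrix(x)
  p <- ncol(x)
  if (length(k) == 1L && p > 1L) k <- rep(k, p)
  if (length(k) != p) {
    stop("length of `k` (", length(k), ") must equal the number of ",
         "predictors (", p, ")", call. = FALSE)
  }
  k <- as.integer(k)
  if (anyNA(k) || any(k < 0L)) {
    stop("`k` must be non-negative integers", call. = FALSE)
  }

  nm <- colnames(x)
  n <- nrow(x)
  m <- 1L + p + sum(k)

  if (isTRUE(rescale)) {
    if (is.null(ranges)) ranges <- apply(x, 2L, range)
    ranges <- matrix(as.numeric(ranges), nrow = 2L)
    if (ncol(ranges) != p || any(ranges[2L, ] <= ranges[1L, ])) {
      stop("`ranges` must be a 2 x p matrix with low < high", call. = FALSE)
    }
    xc <- sweep(x, 2L, ranges[1L, ], `-`)
    xc <- sweep(xc, 2L, ranges[2L, ] - ranges[1L, ], `/`) * pi
  } else {
    ranges <- NULL
    xc <- x
  }

  Z <- matrix(0, n, m)
  type <- character(m); pred <- integer(m); harm <- integer(m)
  cn <- character(m)
  Z[, 1L] <- 0.5
  type[1L] <- "intercept"; pred[1L] <- NA_integer_; harm[1L] <- NA_integer_
  cn[1L] <- "a0"
  col <- 2L
  for (j in seq_len(p)) {
    Z[, col] <- x[, j]
    type[col] <- "linear"; pred[col] <- j; harm[col] <- NA_integer_
    cn[col] <- nm[j]
    col <- col + 1L
    for (kk in seq_len(k[j])) {
      Z[, col] <- cos(kk * xc[, j])
      type[col] <- "cosine"; pred[col] <- j; harm[col] <- kk
      cn[col] <- sprintf("cos(%d*%s)", kk, nm[j])
      col <- col + 1L
    }
  }
  colnames(Z) <- cn

  structure(Z,
            combo = k,
            terms = data.frame(column = cn, type = type, predictor = pred,
                               harmonic = harm, stringsAsFactors = FALSE),
            predictors = nm,
            rescale = isTRUE(rescale),
            ranges = ranges,
            class = c("fs_design", "matrix", "array"))
}

# Validate and coerce predictors to a plain numeric matrix with names.
as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("predictors must be a numeric matrix or data frame", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("predictor matrix must have at least one row and one column",
         call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x))
    stop("non-finite predictor value at row ", rc[1L], ", column ", rc[2L],
         " (", length(bad), " offending entr",
         if (length(bad) == 1L) "y" else "ies", " in total)", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

#' @export
print.fs_design <- function(x, ...) {
  tm <- attr(x, "terms")
  cat("Fourier-series design matrix: ", nrow(x), " x ", ncol(x),
      " (K = ", paste(attr(x, "combo"), collapse = ","), ")\n", sep = "")
  cat("columns:", paste(tm$column, collapse = ", "), "\n")
  invisible(x)
}

#' Linear predictor of a design matrix and coefficient vector
#'
#' Computes \eqn{\eta_i = \sum_c Z_{ic} \beta_c}. `beta` may be a plain
#' numeric vector aligned with the columns of `Z`, or an [fs_coef] block.
#'
#' @param Z design matrix from [fs_design()] (or any numeric matrix).
#' @param beta coefficient vector of length `ncol(Z)`, or an `fs_coef`.
#' @return numeric vector of length `nrow(Z)`.
#' @export
fs_linear_predictor <- function(Z, beta) {
  beta <- as_beta_vector(beta)
  if (length(beta) != ncol(Z)) {
    stop("coefficient length ", length(beta),
         " does not match design columns ", ncol(Z), call. = FALSE)
  }
  drop(Z %*% beta)
}

#' Overflow-safe inverse logit
#'
#' \eqn{\pi = e^\eta / (1 + e^\eta)}, evaluated without overflow for large
#' \eqn{|\eta|} and clamped to the open interval (0, 1) so downstream logs
#' are finite.
#'
#' @param eta numeric vector of linear predictors.
#' @return probabilities strictly inside (0, 1).
#' @examples
#' fs_inv_logit(0)        # 0.5
#' fs_inv_logit(log(3))   # 0.75
#' @export
fs_inv_logit <- function(eta) {
  if (any(!is.finite(eta))) stop("`eta` must be finite", call. = FALSE)
  p <- ifelse(eta >= 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Structured coefficient block for the Fourier-series logit model
#'
#' Bundles the intercept `a0` (paired with the 1/2 basis column), the linear
#' slopes `b` (one per predictor) and the ragged cosine amplitudes `a` (for
#' predictor j, a numeric vector of length \eqn{K_j}; `a[[j]]` may be empty).
#' The block flattens, via [as_beta_vector()], to the column order of
#' [fs_design()].
#'
#' @param a0 intercept coefficient.
#' @param b numeric vector of linear coefficients, length p.
#' @param a list of p numeric vectors of cosine amplitudes (default: all
#'   empty, i.e. K_j = 0 everywhere).
#' @return object of class `"fs_coef"`.
#' @examples
#' beta <- fs_coef(a0 = 2, b = 3, a = list(5))
#' as_beta_vector(beta)  # c(2, 3, 5)
#' @export
fs_coef <- function(a0, b, a = NULL) {
  b <- as.numeric(b)
  p <- length(b)
  if (is.null(a)) a <- rep(list(numeric(0)), p)
  if (!is.list(a)) a <- list(as.numeric(a))
  if (length(a) != p) {
    stop("`a` must be a list with one vector per predictor", call. = FALSE)
  }
  a <- lapply(a, as.numeric)
  structure(list(a0 = as.numeric(a0), b = b, a = a),
            class = "fs_coef")
}

#' Flatten coefficients to design-column order
#'
#' @param beta an `fs_coef` block or a numeric vector (returned as-is).
#' @return numeric vector: `a0`, then per predictor its `b_j` followed by
#'   `a_{1j}, ..., a_{Kj,j}`.
#' @export
as_beta_vector <- function(beta) {
  if (is.numeric(beta)) return(as.numeric(beta))
  if (!inherits(beta, "fs_coef")) {
    stop("`beta` must be numeric or an fs_coef", call. = FALSE)
  }
  out <- beta$a0
  for (j in seq_along(beta$b)) out <- c(out, beta$b[j], beta$a[[j]])
  unname(out)
}

#' @export
print.fs_coef <- function(x, ...) {
  cat("fs_coef: a0 =", format(x$a0), " K =",
      paste(vapply(x$a, length, 1L), collapse = ","), "\n")
  invisible(x)
}

# Split a flat coefficient vector back into blocks given the combo.
split_beta <- function(beta, k) {
  beta <- as.numeric(beta)
  p <- length(k)
  b <- numeric(p); a <- vector("list", p)
  i <- 2L
  for (j in seq_len(p)) {
    b[j] <- beta[i]; i <- i + 1L
    a[[j]] <- if (k[j] > 0L) beta[i:(i + k[j] - 1L)] else numeric(0)
    i <- i + k[j]
  }
  fs_coef(a0 = beta[1L], b = b, a = a)
}

#' Number of parameters of a Fourier-series logit model
#'
#' \eqn{m = 1 + p + \sum_j K_j}: one intercept, one linear slope per
#' predictor, and one amplitude per cosine harmonic.
#'
#' @param k oscillation-parameter vector (length p).
#' @return integer m.
#' @export
fs_n_params <- function(k) {
  k <- as.integer(k)
  if (anyNA(k) || any(k < 0L)) stop("`k` must be non-negative", call. = FALSE)
  1L + length(k) + sum(k)
}
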