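#' Simulate a binary dataset with linear-plus-cosine logit truth
#'
#' Draws predictors independently uniform over per-predictor ranges,
#' computes the true logit through the same cosine-series basis used for
#' fitting,
#' \deqn{\mathrm{logit}\,\pi_i = \tfrac{1}{2}a_0 + \sum_j \big( b_j x_{ji}
#'   + \sum_{k=1}^{K_j} a_{kj}\cos(k x_{ji}) \big),}
#' and samples \eqn{y_i \sim \mathrm{Bernoulli}(\pi_i)}. Everything is
#' reproducible from `seed`; the generator restores the caller's RNG state
#' on exit, so simulation leaves no global side effects.
#'
#' Default ranges are \eqn{[0, 2\pi]} per predictor, over which each
#' harmonic completes full cycles and the cosine columns are (nearly)
#' orthogonal; percentage-like ranges such as \eqn{[0, 100]} can be set to
#' emulate survey-style predictors.
#'
#' @param n sample size.
#' @param beta true coefficients as an [fs_coef] (its `a` lengths define the
#'   true oscillation parameters).
#' @param ranges 2 x p matrix of per-predictor (low, high); default
#'   `[0, 2*pi]` everywhere.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @param names optional predictor names (default x1..xp).
#' @return object of class `"fs_dataset"`: list with `x` (n x p matrix),
#'   `y` (0/1 vector), `true_probs`, `true_eta`, and `spec` (n, beta,
#'   combo, ranges, seed).
#' @examples
#' beta <- fs_coef(a0 = 0.4, b = c(0.5, -0.3),
#'                 a = list(c(1.5, -1), 1.2))
#' d <- fs_simulate(200, beta, seed = 7)
#' mean(d$y)
#' @export
fs_simulate <- function(n, beta, ranges = NULL, seed = NULL, names = NULL) {
  if (!inherits(beta, "fs_coef")) {
    stop("`beta` must be an fs_coef", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  p <- length(beta$b)
  combo <- vapply(beta$a, length, 1L)
  if (is.null(ranges)) ranges <- matrix(rep(c(0, 2 * pi), p), nrow = 2L)
  ranges <- matrix(as.numeric(ranges), nrow = 2L)
  if (ncol(ranges) != p) {
    stop("`ranges` must have one column per predictor", call. = FALSE)
  }
  if (any(ranges[2L, ] <= ranges[1L, ])) {
    stop("each range must satisfy low < high", call. = FALSE)
  }
  if (is.null(names)) names <- paste0("x", seq_len(p))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }

  x <- vapply(seq_len(p),
              function(j) stats::runif(n, ranges[1L, j], ranges[2L, j]),
              numeric(n))
  x <- matrix(x, nrow = n, dimnames = list(NULL, names))
  Z <- fs_design(x, combo)
  eta <- fs_linear_predictor(Z, beta)
  probs <- fs_inv_logit(eta)
  y <- stats::rbinom(n, 1L, probs)

  structure(list(x = x, y = y, true_probs = probs, true_eta = eta,
                 spec = list(n = n, beta = beta, combo = combo,
                             ranges = ranges, seed = seed)),
            class = "fs_dataset")
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat("Synthetic binary dataset: n = ", x$spec$n, ", p = ",
      ncol(x$x), ", true K = (", paste(x$spec$combo, collapse = ","),
      "), mean(y) = ", round(mean(x$y), 3), "\n", sep = "")
  invisible(x)
}

#' Write a dataset (or any x/y pair) to CSV
#'
#' Response column first (named `y`), predictors after, with header;
#' re-reading with [fs_read_dataset()] round-trips the values.
#'
#' @param data an `fs_dataset`, or a list with elements `x` and `y`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
fs_write_dataset <- function(data, path) {
  df <- data.frame(y = data$y, data$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate the standard fixture suite
#'
#' Writes four small seeded CSV datasets spanning the regimes the model
#' must handle — a null model (all coefficients zero), a linear-only
#' logistic truth, a cosine-dominant truth, and a steep near-separated
#' truth — plus a JSON manifest recording each file's seed, sample size and
#' true coefficients so tests can reuse the ground truth.
#'
#' @param out_dir writable output directory (created if missing).
#' @return manifest as a named list, invisibly; files land in `out_dir`.
#' @export
fs_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("directory not writable: ", out_dir, call. = FALSE)
  }

  specs <- list(
    null = list(n = 200L, seed = 101L,
                beta = fs_coef(0, c(0, 0), list(0, 0))),
    linear = list(n = 300L, seed = 102L,
                  beta = fs_coef(0.8, c(0.6, -0.5))),
    cosine = list(n = 400L, seed = 103L,
                  beta = fs_coef(0.4, c(0.3, 0),
                                 a = list(c(1.8, -1.2), 1.5))),
    near_separated = list(n = 80L, seed = 104L,
                          beta = fs_coef(-24, 8))
  )

  manifest <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    d <- fs_simulate(sp$n, sp$beta, seed = sp$seed)
    f <- file.path(out_dir, paste0(nm, ".csv"))
    fs_write_dataset(d, f)
    manifest[[nm]] <- list(
      file = basename(f), n = sp$n, seed = sp$seed,
      combo = as.integer(d$spec$combo),
      a0 = sp$beta$a0, b = sp$beta$b, a = sp$beta$a)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
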