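#' Read a binary-response dataset from CSV
#'
#' Reads a comma-separated file with a header row, validates that the
#' response column is strictly coded 0/1 and that every predictor is
#' numeric, finite and complete. Missing or non-numeric cells are an error
#' that lists the offending rows — the method requires complete data; any
#' imputation or screening happens upstream.
#'
#' @param path CSV file path.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names; default
#'   all remaining columns.
#' @return list with `x` (numeric matrix) and `y` (0/1 vector).
#' @export
fs_read_dataset <- function(path, response = "y", predictors = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found in ", path,
         call. = FALSE)
  }
  if (is.null(predictors)) predictors <- setdiff(names(df), response)
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols)) {
    stop("unknown predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!length(predictors)) stop("no predictor columns", call. = FALSE)

  y <- df[[response]]
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    bad <- which(is.na(y) | !(suppressWarnings(as.numeric(y)) %in% c(0, 1)))
    stop("response column '", response, "' must be coded 0/1; ",
         "offending rows: ", paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", call. = FALSE)
  }

  xdf <- df[predictors]
  for (cc in predictors) {
    v <- xdf[[cc]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("missing or non-numeric values in column '", cc,
           "' at row(s): ", paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) ", ..." else "", call. = FALSE)
    }
    xdf[[cc]] <- v
  }
  x <- as.matrix(xdf)
  list(x = x, y = as.numeric(y))
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full modelling pipeline
#'
#' End-to-end workflow on one dataset: minimum-AIC oscillation-parameter
#' search, refit of the best cosine-series model, the binary-logistic
#' baseline, model comparison with classification metrics, and a structured
#' JSON report (selection table, coefficient tables for both models,
#' deviance / classification comparison). Progress is logged to stderr with
#' timestamps; the report payload itself carries no timestamps, so repeated
#' runs with the same inputs are byte-identical.
#'
#' @param input path to a CSV dataset (see [fs_read_dataset()]).
#' @param response,predictors column selection for [fs_read_dataset()].
#' @param k_max,k_min search bounds for [fs_select()].
#' @param cutoff classification threshold for [fs_compare()].
#' @param rescale map predictors to \eqn{[0, \pi]} inside cosines.
#' @param eps,max_iter Newton-Raphson controls.
#' @param output optional path for the JSON report.
#' @return the report as a named list, invisibly.
#' @export
fs_pipeline <- function(input, response = "y", predictors = NULL,
                        k_max = 4L, k_min = 1L, cutoff = 0.5,
                        rescale = FALSE, eps = 1e-6, max_iter = 100L,
                        output = NULL) {
  log_msg("reading ", input)
  d <- fs_read_dataset(input, response, predictors)
  log_msg("n = ", nrow(d$x), ", p = ", ncol(d$x),
          "; searching K in ", k_min, "..", k_max,
          " (", (k_max - k_min + 1L)^ncol(d$x), " combinations)")
  sel <- fs_select(d$x, d$y, k_max = k_max, k_min = k_min,
                   rescale = rescale, eps = eps, max_iter = max_iter)
  log_msg("best combination (", paste(sel$best_combo, collapse = ","),
          "), AIC = ", format(sel$best_aic, digits = 8))
  fit_fs <- sel$best_fit
  log_msg("fitting binary-logistic baseline")
  fit_bl <- fs_fit_logistic(d$x, d$y, eps = eps, max_iter = max_iter)
  for (f in list(fit_fs, fit_bl)) {
    if (!f$converged) log_msg("warning: a fit did not converge")
  }
  cmp <- fs_compare(list(fourier = fit_fs, logistic = fit_bl), d$y,
                    cutoff = cutoff)

  report <- list(
    input = basename(input),
    n = nrow(d$x), p = ncol(d$x),
    selection = list(
      method = sel$method, k_min = k_min, k_max = k_max,
      levels = sel$levels, table = sel$table,
      best_combo = sel$best_combo, best_aic = sel$best_aic),
    fourier = fit_report(fit_fs),
    logistic = fit_report(fit_bl),
    comparison = cmp$table,
    best_deviance = cmp$best_deviance,
    best_auc = cmp$best_auc,
    cutoff = cutoff
  )
  if (!is.null(output)) {
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    log_msg("report written to ", output)
  }
  invisible(report)
}

fit_report <- function(fit) {
  list(model = fit$model,
       combo = if (!is.null(fit$combo)) as.integer(fit$combo),
       coefficients = as.list(fit$coefficients),
       loglik = fit$loglik, deviance = fit$deviance, aic = fit$aic,
       n_iter = fit$n_iter, converged = fit$converged)
}

#' Command-line interface
#'
#' Subcommand dispatcher used by the `exec/fslogit` script:
#' \describe{
#'   \item{fit}{`fslogit fit --input data.csv --response y --combo 3,2,1,1,1,1`}
#'   \item{select}{`fslogit select --input data.csv --k-max 4`}
#'   \item{evaluate}{`fslogit evaluate --input data.csv --combo 2,1 --cutoff 0.5`}
#'   \item{simulate}{`fslogit simulate --n 500 --b 0.5,-0.3 --a 1.5:-1,1.2 --seed 7 --output out.csv`}
#' }
#' Reports go to `--output` (JSON) or stdout; logs to stderr. Returns an
#' exit status (0 on success) rather than calling `quit()`, so it is
#' testable in-process.
#'
#' @param args character vector of command-line arguments (the first being
#'   the subcommand).
#' @return integer exit status, invisibly.
#' @export
fs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      stop("usage: fslogit <fit|select|evaluate|simulate> [options]",
           call. = FALSE)
    }
    cmd <- args[[1L]]
    rest <- args[-1L]
    switch(cmd,
           fit = cli_fit(rest),
           select = cli_select(rest),
           evaluate = cli_evaluate(rest),
           simulate = cli_simulate(rest),
           stop("unknown subcommand '", cmd, "'", call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_combo <- function(s) as.integer(strsplit(s, ",")[[1L]])

cli_common_opts <- function() {
  list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--response", type = "character", default = "y"),
    optparse::make_option("--output", type = "character", default = NULL),
    optparse::make_option("--cutoff", type = "double", default = 0.5),
    optparse::make_option("--rescale", action = "store_true",
                          default = FALSE),
    optparse::make_option("--eps", type = "double", default = 1e-6),
    optparse::make_option("--max-iter", type = "integer", default = 100L,
                          dest = "max_iter")
  )
}

cli_emit <- function(obj, output) {
  if (is.null(output)) {
    cat(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE), "\n")
  } else {
    jsonlite::write_json(obj, output, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    log_msg("written ", output)
  }
}

cli_fit <- function(args) {
  opts <- c(cli_common_opts(),
            list(optparse::make_option("--combo", type = "character",
                                       default = NULL)))
  o <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                            args = args)
  if (is.null(o$input)) stop("--input is required", call. = FALSE)
  d <- fs_read_dataset(o$input, o$response)
  k <- if (is.null(o$combo)) rep(0L, ncol(d$x)) else parse_combo(o$combo)
  fit <- fs_fit(d$x, d$y, k = k, rescale = o$rescale, eps = o$eps,
                max_iter = o$max_iter)
  cli_emit(fit_report(fit), o$output)
}

cli_select <- function(args) {
  opts <- c(cli_common_opts(),
            list(optparse::make_option("--k-max", type = "integer",
                                       default = 4L, dest = "k_max"),
                 optparse::make_option("--k-min", type = "integer",
                                       default = 1L, dest = "k_min")))
  o <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                            args = args)
  if (is.null(o$input)) stop("--input is required", call. = FALSE)
  rep_ <- fs_pipeline(o$input, o$response, k_max = o$k_max,
                      k_min = o$k_min, cutoff = o$cutoff,
                      rescale = o$rescale, eps = o$eps,
                      max_iter = o$max_iter, output = o$output)
  if (is.null(o$output)) cli_emit(rep_, NULL)
}

cli_evaluate <- function(args) {
  opts <- c(cli_common_opts(),
            list(optparse::make_option("--combo", type = "character",
                                       default = NULL)))
  o <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                            args = args)
  if (is.null(o$input)) stop("--input is required", call. = FALSE)
  d <- fs_read_dataset(o$input, o$response)
  k <- if (is.null(o$combo)) rep(1L, ncol(d$x)) else parse_combo(o$combo)
  fit <- fs_fit(d$x, d$y, k = k, rescale = o$rescale, eps = o$eps,
                max_iter = o$max_iter)
  bl <- fs_fit_logistic(d$x, d$y, eps = o$eps, max_iter = o$max_iter)
  cmp <- fs_compare(list(fourier = fit, logistic = bl), d$y,
                    cutoff = o$cutoff)
  cli_emit(list(comparison = cmp$table,
                best_deviance = cmp$best_deviance,
                best_auc = cmp$best_auc), o$output)
}

cli_simulate <- function(args) {
  opts <- list(
    optparse::make_option("--n", type = "integer", default = 500L),
    optparse::make_option("--a0", type = "double", default = 0),
    optparse::make_option("--b", type = "character", default = "0"),
    optparse::make_option("--a", type = "character", default = NULL,
                          help = "cosine amplitudes: ':' within predictor, ',' between, e.g. 1.5:-1,1.2"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--output", type = "character", default = NULL)
  )
  o <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                            args = args)
  b <- as.numeric(strsplit(o$b, ",")[[1L]])
  a <- if (is.null(o$a)) NULL else {
    lapply(strsplit(o$a, ",")[[1L]], function(s) {
      if (nzchar(s)) as.numeric(strsplit(s, ":")[[1L]]) else numeric(0)
    })
  }
  d <- fs_simulate(o$n, fs_coef(o$a0, b, a), seed = o$seed)
  if (is.null(o$output)) o$output <- "simulated.csv"
  fs_write_dataset(d, o$output)
  log_msg("wrote ", o$output, " (n = ", o$n, ", mean(y) = ",
          round(mean(d$y), 3), ")")
}
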