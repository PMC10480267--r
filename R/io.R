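#' Read a GROMACS-style XVG series file
#'
#' Lines starting with `#` or `@` are treated as comments/metadata;
#' whitespace-separated numeric rows are parsed into a matrix. Column
#' legends are recovered from `@ sN legend "..."` metadata when present;
#' the first column is the time column.
#'
#' @param path file path.
#' @return an object of class `series_file`: `data` (numeric matrix,
#'   first column time), `labels` (column labels), `comments` (the
#'   metadata lines).
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*[#@]", lines)
  blank <- !nzchar(trimws(lines))
  data_lines <- which(!is_comment & !blank)
  if (length(data_lines) == 0) stop(sprintf("no data rows in %s", path))
  rows <- strsplit(trimws(lines[data_lines]), "\\s+")
  ncols <- length(rows[[1]])
  mat <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncols)
      stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                   data_lines[i], path, length(rows[[i]]), ncols))
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric value at line %d of %s", data_lines[i], path))
    mat[i, ] <- vals
  }
  comments <- lines[is_comment]
  legends <- regmatches(comments,
                        regexec("^@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"",
                                comments))
  labels <- c("time", rep(NA_character_, ncols - 1L))
  for (lg in legends) {
    if (length(lg) == 3L) {
      idx <- as.integer(lg[2]) + 2L
      if (idx <= ncols) labels[idx] <- lg[3]
    }
  }
  structure(list(data = mat, labels = labels, comments = comments,
                 path = path),
            class = "series_file")
}

#' @export
print.series_file <- function(x, ...) {
  cat(sprintf("series_file: %d rows x %d columns (%s)\n", nrow(x$data),
              ncol(x$data), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Write a matrix of series data in the XVG dialect
#'
#' @param data numeric matrix, first column time.
#' @param path output file.
#' @param labels optional legends for the value columns.
#' @param comments extra comment lines (written with a leading `#`).
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(data, path, labels = NULL, comments = character(0),
                      force = FALSE) {
  if (file.exists(path) && !force)
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  data <- as.matrix(data)
  hdr <- c(paste0("# ", comments),
           "@    xaxis  label \"Time\"")
  if (!is.null(labels))
    hdr <- c(hdr, sprintf("@ s%d legend \"%s\"", seq_along(labels) - 1L,
                          labels))
  body <- apply(data, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a series file to a force series
#'
#' @param sf a [read_xvg()] result or path to an XVG/CSV file.
#' @param lambda the lambda vector the series was sampled at.
#' @param discard number of initial samples to discard as equilibration.
#' @return a [force_series()]; `dt` is taken from the time column spacing.
#' @export
force_series_from_file <- function(sf, lambda, discard = 0L) {
  if (is.character(sf)) {
    sf <- if (grepl("\\.csv$", sf, ignore.case = TRUE)) {
      d <- as.matrix(read.table(sf, header = TRUE, sep = ","))
      structure(list(data = d, labels = colnames(d)), class = "series_file")
    } else read_xvg(sf)
  }
  d <- sf$data
  if (nrow(d) < 2L) stop("series file too short")
  times <- d[, 1L]
  if (any(diff(times) <= 0)) stop("time column must be strictly increasing")
  keep <- seq.int(discard + 1L, nrow(d))
  force_series(d[keep, -1L, drop = FALSE], dt = mean(diff(times)),
               lambda = lambda, discarded = discard)
}

#' Write a metric profile or 2D field as CSV
#'
#' 1D profiles are written as `lambda, value, stderr`; tensor estimates and
#' fields in long format `lambda1, lambda2, g11, g12, g22, sqrt_det`.
#' Deterministic column order, full float precision.
#'
#' @param x a [metric_estimate()] or `metric_field`.
#' @param path output file.
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  if (inherits(x, "metric_field")) x <- x$estimate
  stopifnot(inherits(x, "metric_estimate"))
  if (is_tensor_metric(x)) {
    df <- data.frame(lambda1 = x$lambda[, 1L], lambda2 = x$lambda[, 2L],
                     g11 = x$value[, 1, 1], g12 = x$value[, 1, 2],
                     g22 = x$value[, 2, 2],
                     sqrt_det = sqrt_det_metric(x))
  } else {
    df <- data.frame(lambda = x$lambda[, 1L], value = x$value,
                     stderr = if (is.null(x$se)) NA_real_ else x$se)
  }
  write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a metric estimate as JSON
#'
#' Serializes the lambda grid, values (tensors in long form), standard
#' errors and estimator tag.
#'
#' @param x a [metric_estimate()].
#' @param path output file.
#' @param force overwrite an existing file.
#' @return `path` invisibly (write); a [metric_estimate()] (read).
#' @export
write_metric_json <- function(x, path, force = FALSE) {
  stopifnot(inherits(x, "metric_estimate"))
  if (file.exists(path) && !force)
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  obj <- list(estimator = x$estimator,
              lambda = as.data.frame(x$lambda),
              tensor = is_tensor_metric(x),
              clipped = x$clipped)
  if (is_tensor_metric(x)) {
    obj$g11 <- x$value[, 1, 1]; obj$g12 <- x$value[, 1, 2]
    obj$g22 <- x$value[, 2, 2]
  } else {
    obj$value <- x$value
    obj$se <- if (is.null(x$se)) rep(NA_real_, length(x$value)) else x$se
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_metric_json
#' @export
read_metric_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lam <- as.matrix(obj$lambda)
  dimnames(lam) <- NULL
  if (isTRUE(obj$tensor)) {
    np <- nrow(lam)
    val <- array(NA_real_, c(np, 2, 2))
    val[, 1, 1] <- obj$g11
    val[, 1, 2] <- val[, 2, 1] <- obj$g12
    val[, 2, 2] <- obj$g22
    return(metric_estimate(lam, val, estimator = obj$estimator,
                           clipped = obj$clipped))
  }
  metric_estimate(lam, obj$value, se = obj$se, estimator = obj$estimator,
                  clipped = obj$clipped)
}

#' Read a 1D metric profile from CSV
#'
#' @param path a CSV written by [write_metric_csv()].
#' @param estimator estimator tag to attach.
#' @return a [metric_estimate()].
#' @export
read_metric_csv <- function(path, estimator = "friction") {
  df <- read.table(path, header = TRUE, sep = ",")
  if (all(c("lambda1", "lambda2", "g11") %in% names(df))) {
    np <- nrow(df)
    val <- array(NA_real_, c(np, 2, 2))
    val[, 1, 1] <- df$g11; val[, 1, 2] <- val[, 2, 1] <- df$g12
    val[, 2, 2] <- df$g22
    return(metric_estimate(cbind(df$lambda1, df$lambda2), val,
                           estimator = estimator))
  }
  metric_estimate(df$lambda, df$value, se = df$stderr, estimator = estimator)
}

#' Write / read a lambda path as CSV
#'
#' Columns `s, lambda1, ..., lambdaD`.
#'
#' @param path_obj a [lambda_path()].
#' @param path output file.
#' @param force overwrite an existing file.
#' @return `path` invisibly (write); a [lambda_path()] (read).
#' @export
write_path_csv <- function(path_obj, path, force = FALSE) {
  stopifnot(inherits(path_obj, "lambda_path"))
  if (file.exists(path) && !force)
    stop(sprintf("%s exists; use force = TRUE to overwrite", path))
  df <- data.frame(s = path_obj$s, path_obj$points)
  names(df) <- c("s", paste0("lambda", seq_len(path_obj$n_dims)))
  write.table(format(df, digits = 17, trim = TRUE),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  lambda_path(as.matrix(df[, -1L, drop = FALSE]), s = df$s)
}

#' Validated run configuration
#'
#' Reads a YAML run configuration and validates it against the package's
#' schema; unknown keys are rejected. See the package README for the
#' format.
#'
#' @param path YAML file path.
#' @return an object of class `run_config` (a named list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

run_config_schema <- list(
  system = c("kind", "k_A", "k_B", "n_oscillators", "n_solvent", "box", "epsilon_ss",
             "sigma_ss", "epsilon_solute", "sigma_solute", "charge",
             "k_tether", "r0", "epsilon", "sigma", "q1", "channel_strength",
             "alpha", "p"),
  thermo = c("temperature"),
  lambda = c("n_points", "n_dims", "path", "channel"),
  sampler = c("timestep", "friction_gamma", "n_steps", "sample_interval",
              "move_kind", "lambda_move_interval", "equil_fraction",
              "n_walkers"),
  bias = c("target", "initial_error", "update_interval", "n_updates",
           "covering_threshold", "target_floor", "min_target_interval"),
  estimator = NULL,
  evaluation = c("n_repeats", "seed", "n_boot"),
  output = NULL)

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping")
  unknown <- setdiff(names(cfg), names(run_config_schema))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")))
  for (sec in names(cfg)) {
    keys <- run_config_schema[[sec]]
    if (is.null(keys)) next
    if (!is.list(cfg[[sec]]))
      stop(sprintf("config section '%s' must be a mapping", sec))
    bad <- setdiff(names(cfg[[sec]]), keys)
    if (length(bad))
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$system$kind) ||
      !cfg$system$kind %in% c("harmonic", "micro_solvation", "two_lambda"))
    stop("config: system.kind must be harmonic, micro_solvation or two_lambda")
  structure(cfg, class = "run_config")
}

build_system_from_config <- function(cfg) {
  sc <- cfg$system
  args <- sc[setdiff(names(sc), "kind")]
  switch(sc$kind,
         harmonic = do.call(harmonic_system, args),
         micro_solvation = do.call(micro_solvation_system, args),
         two_lambda = do.call(two_lambda_system, args))
}
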