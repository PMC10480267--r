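#' Adaptive weight-histogram bias for expanded-ensemble sampling
#'
#' State of the adaptive bias: free-energy estimates `f_lambda`
#' (dimensionless; they converge to `beta G_lambda` up to a constant), the
#' target distribution `pi_lambda`, the accumulated weight histogram, and
#' the two-stage update machinery. The first stage uses a robust
#' constant-size update with histogram-covering checks that repeatedly halve
#' the update size; the second stage uses a stochastic-approximation update
#' whose standard error decays like `1/sqrt(N)`.
#'
#' @param lambda lambda grid: numeric vector (1D) or matrix (one row per
#'   point).
#' @param target `"uniform"` or a positive numeric vector over the grid
#'   (renormalized with a warning if it does not sum to one).
#' @param initial_error initial free-energy error scale (energy units, > 0);
#'   the initial update size is `beta * initial_error / n_points`.
#' @param thermo a [thermo_params()].
#' @param update_interval number of accumulated lambda samples per bias
#'   update.
#' @param covering_threshold a covering epoch completes when every point's
#'   epoch histogram exceeds this fraction of its target share.
#' @param target_floor dynamic-target floor, as a fraction of the maximum
#'   `sqrt(det g)` (prevents starvation of end points).
#' @param min_target_interval minimum number of bias updates between dynamic
#'   target updates.
#' @return an object of class `awh_bias`.
#' @export
awh_bias <- function(lambda, target = "uniform", initial_error = 10,
                     thermo = thermo_params(), update_interval = 50L,
                     covering_threshold = 0.2, target_floor = 0.05,
                     min_target_interval = 5L) {
  grid <- if (is.matrix(lambda)) lambda else matrix(as.numeric(lambda), ncol = 1L)
  np <- nrow(grid)
  if (np < 1L) stop("lambda grid must be nonempty")
  if (initial_error <= 0) stop("initial_error must be positive")
  thermo <- as_thermo(thermo)
  if (identical(target, "uniform")) {
    pi_t <- rep(1 / np, np)
  } else {
    pi_t <- as.numeric(target)
    if (length(pi_t) != np || any(!is.finite(pi_t)) || any(pi_t <= 0))
      stop("target must be a positive vector over the lambda grid")
    if (abs(sum(pi_t) - 1) > 1e-12) {
      warning("target distribution renormalized to sum to 1")
      pi_t <- pi_t / sum(pi_t)
    }
  }
  delta0 <- thermo$beta * initial_error / np
  structure(list(grid = grid, f = rep(0, np), target = pi_t,
                 hist = rep(0, np), hist_epoch = rep(0, np),
                 visits = rep(0, np),
                 n_since_update = 0, n_total = 0, n_updates = 0L,
                 stage = "initial", delta = delta0, delta0 = delta0,
                 n_halvings = 0L, n_eff = NA_real_,
                 update_interval = as.integer(update_interval),
                 covering_threshold = covering_threshold,
                 target_floor = target_floor,
                 min_target_interval = as.integer(min_target_interval),
                 last_target_update = -Inf,
                 beta = thermo$beta, initial_error = initial_error,
                 dg_trace = numeric(0), stage_trace = character(0),
                 final_start = NA_integer_),
            class = "awh_bias")
}

#' @export
print.awh_bias <- function(x, ...) {
  cat(sprintf("awh_bias: %d points, stage %s, %d updates, update size %.3g\n",
              nrow(x$grid), x$stage, x$n_updates, x$delta))
  invisible(x)
}

#' Accumulate lambda samples into the bias histogram
#'
#' Adds one conditional-weight vector (or a pre-summed histogram of `n`
#' samples) to the weight histogram. Interleaved accumulation from several
#' walkers is additive.
#'
#' @param bias an [awh_bias()].
#' @param w non-negative weight vector over the grid; a single sample sums
#'   to one.
#' @param n number of samples represented by `w` (default 1).
#' @return the updated bias.
#' @export
awh_accumulate <- function(bias, w, n = 1L) {
  stopifnot(inherits(bias, "awh_bias"), length(w) == nrow(bias$grid),
            all(w >= 0))
  bias$hist <- bias$hist + w
  bias$hist_epoch <- bias$hist_epoch + w
  bias$n_since_update <- bias$n_since_update + n
  bias$n_total <- bias$n_total + n
  bias
}

#' Apply one bias update
#'
#' Normalized stochastic-approximation update
#' `f <- f - Delta * (h / (sum(h) * pi) - 1)` on the weight histogram `h`
#' accumulated since the previous update. In the initial stage `Delta` is
#' the current (halving) update size; in the final stage
#' `Delta = m / N_eff` with `m` the epoch sample count, so the error decays
#' as `1/sqrt(N)`. The histogram is reset, the gauge `f[1] = 0` re-fixed,
#' and stage transitions are checked.
#'
#' @param bias an [awh_bias()] with at least one accumulated sample.
#' @return the updated bias.
#' @export
awh_update <- function(bias) {
  stopifnot(inherits(bias, "awh_bias"))
  if (bias$n_since_update == 0) {
    warning("awh_update called with no accumulated samples; no-op")
    return(bias)
  }
  h <- bias$hist / sum(bias$hist)
  if (bias$stage == "final") {
    bias$n_eff <- bias$n_eff + bias$n_since_update
    bias$delta <- bias$n_since_update / bias$n_eff
  }
  bias$f <- bias$f - bias$delta * (h / bias$target - 1)
  bias$f <- bias$f - bias$f[1L]
  bias$hist <- rep(0, nrow(bias$grid))
  bias$n_since_update <- 0
  bias$n_updates <- bias$n_updates + 1L
  bias$dg_trace <- c(bias$dg_trace, bias$f[nrow(bias$grid)] - bias$f[1L])
  bias$stage_trace <- c(bias$stage_trace, bias$stage)
  if (bias$stage == "initial") bias <- awh_check_initial_stage(bias)
  bias
}

#' Covering check and initial-stage exit
#'
#' A covering epoch completes when every grid point's epoch histogram
#' exceeds `covering_threshold * pi * n_epoch_samples`; each covering halves
#' the update size and resets the epoch histogram. The bias leaves the
#' initial stage when the update size drops to the final-stage size implied
#' by the total sample count, `update_interval / N_total`; from then on the
#' stage flag never returns to `"initial"`.
#'
#' @param bias an [awh_bias()].
#' @return the (possibly modified) bias; inspect `bias$stage` and
#'   `bias$n_halvings`.
#' @export
awh_check_initial_stage <- function(bias) {
  stopifnot(inherits(bias, "awh_bias"))
  if (bias$stage != "initial") return(bias)
  n_epoch <- sum(bias$hist_epoch)
  if (n_epoch > 0) {
    covered <- all(bias$hist_epoch >=
                     bias$covering_threshold * bias$target * n_epoch)
    if (covered) {
      bias$delta <- bias$delta / 2
      bias$n_halvings <- bias$n_halvings + 1L
      bias$hist_epoch <- rep(0, nrow(bias$grid))
    }
  }
  if (bias$n_total > 0 && bias$delta <= bias$update_interval / bias$n_total) {
    bias$stage <- "final"
    bias$n_eff <- bias$update_interval / bias$delta
    bias$final_start <- bias$n_updates + 1L
  }
  bias
}

#' Metric-optimized dynamic target update
#'
#' Sets the target distribution to
#' `pi_lambda` proportional to `max(sqrt(det g(lambda)), floor * max sqrt(det g))`
#' on the bias grid. Only acts in the final stage, and no more often than
#' every `min_target_interval` bias updates; earlier calls are no-ops.
#'
#' @param bias an [awh_bias()] in the final stage.
#' @param metric a [metric_estimate()] on the same grid (scalar in 1D, 2x2
#'   tensors in 2D).
#' @param floor override of the bias' target floor fraction.
#' @return the bias with an updated (normalized) target.
#' @export
awh_dynamic_target <- function(bias, metric, floor = NULL) {
  stopifnot(inherits(bias, "awh_bias"), inherits(metric, "metric_estimate"))
  if (bias$stage != "final") return(bias)
  if (bias$n_updates - bias$last_target_update < bias$min_target_interval)
    return(bias)
  floor <- floor %||% bias$target_floor
  s <- sqrt_det_metric(metric)
  if (length(s) != nrow(bias$grid))
    stop("metric grid does not match the bias grid")
  s[!is.finite(s)] <- 0
  if (max(s) <= 0) {
    warning("all-zero metric; falling back to a uniform target")
    pi_t <- rep(1 / length(s), length(s))
  } else {
    pi_t <- pmax(s, floor * max(s))
    pi_t <- pi_t / sum(pi_t)
  }
  bias$target <- pi_t
  bias$last_target_update <- bias$n_updates
  bias
}

#' Free energy difference from the bias
#'
#' `dG = (f_last - f_first) / beta` under the gauge `f[1] = 0`. The standard
#' error is estimated by block averaging the final-stage trace of
#' `f_last - f_first` (last half of the trace, 8 blocks); it is `NA` while
#' the bias is still in the initial stage.
#'
#' @param bias an [awh_bias()].
#' @param thermo a [thermo_params()]; defaults to the beta stored in the
#'   bias.
#' @param estimator `"last"` uses the current `f`; `"tail_mean"` averages
#'   the final-stage trace over its last quarter, which suppresses the
#'   update-to-update fluctuations of `f`.
#' @return a [free_energy_result()].
#' @export
awh_free_energy <- function(bias, thermo = NULL,
                            estimator = c("last", "tail_mean")) {
  stopifnot(inherits(bias, "awh_bias"))
  estimator <- match.arg(estimator)
  beta <- if (is.null(thermo)) bias$beta else as_thermo(thermo)$beta
  np <- nrow(bias$grid)
  dg <- (bias$f[np] - bias$f[1L]) / beta
  if (estimator == "tail_mean" && !is.na(bias$final_start) &&
      bias$n_updates > bias$final_start) {
    lo <- max(bias$final_start, floor(0.75 * bias$n_updates))
    dg <- mean(bias$dg_trace[seq.int(lo, bias$n_updates)]) / beta
  }
  se <- NA_real_
  if (!is.na(bias$final_start) && bias$n_updates >= bias$final_start + 7L) {
    tr <- bias$dg_trace[seq.int(bias$final_start, bias$n_updates)]
    tr <- tail(tr, max(8L, ceiling(length(tr) / 2)))
    nb <- 8L
    blocks <- split(tr, cut(seq_along(tr), nb, labels = FALSE))
    bm <- vapply(blocks, mean, numeric(1))
    se <- sd(bm) / sqrt(length(bm)) / beta
  }
  free_energy_result(dg, se, method = "awh",
                     breakdown = list(f = bias$f, stage = bias$stage))
}

#' Serialize / restore the bias state
#'
#' Writes (or reads) the grid, free energies, target, histogram and stage
#' bookkeeping as JSON for restart and inspection.
#'
#' @param bias an [awh_bias()].
#' @param path file path.
#' @return `awh_save` returns `path` invisibly; `awh_load` returns the
#'   restored [awh_bias()].
#' @export
awh_save <- function(bias, path) {
  stopifnot(inherits(bias, "awh_bias"))
  x <- unclass(bias)
  x$grid <- as.data.frame(x$grid)
  if (!is.finite(x$last_target_update)) x$last_target_update <- NULL
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname awh_save
#' @export
awh_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$grid <- as.matrix(x$grid)
  dimnames(x$grid) <- NULL
  x$last_target_update <- x$last_target_update %||% -Inf
  x$dg_trace <- as.numeric(x$dg_trace)
  x$stage_trace <- as.character(x$stage_trace)
  x$final_start <- if (is.null(x$final_start)) NA_integer_ else x$final_start
  class(x) <- "awh_bias"
  x
}
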