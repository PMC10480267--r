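#' Sampler settings
#'
#' Settings for the overdamped Langevin / Metropolis configuration sampler
#' and the expanded-ensemble lambda moves. With overdamped Langevin the
#' update is
#' \deqn{x' = x - (\Delta t/\gamma) \nabla H(x;\lambda)
#'       + \sqrt{2\Delta t/(\beta\gamma)}\,\xi,}
#' with standard-normal noise. Identical seeds give identical trajectories.
#'
#' @param timestep integration timestep (> 0).
#' @param friction_gamma friction coefficient gamma (> 0).
#' @param n_steps number of configuration steps per fixed-lambda run.
#' @param sample_interval record every this many steps (fixed lambda) or
#'   lambda moves (expanded ensemble).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param move_kind `"langevin"` (Euler-Maruyama), `"metropolis"`, or
#'   `"exact_ou"` (the exact Ornstein-Uhlenbeck propagator of the same
#'   overdamped dynamics; harmonic systems only, no timestep
#'   discretization error).
#' @param mc_step Metropolis displacement half-width (defaults to
#'   `sqrt(2 timestep / (beta gamma))` at beta = 1).
#' @param equil_fraction fraction of each fixed-lambda series discarded as
#'   equilibration (default 0.1).
#' @param lambda_move_interval configuration steps per lambda move in
#'   expanded-ensemble runs (default 10).
#' @param n_walkers number of communicating walkers sharing one bias.
#' @return an object of class `sampler_settings`.
#' @export
sampler_settings <- function(timestep = 0.01, friction_gamma = 1,
                             n_steps = 10000L, sample_interval = 10L,
                             seed = NULL,
                             move_kind = c("langevin", "metropolis", "exact_ou"),
                             mc_step = NULL, equil_fraction = 0.1,
                             lambda_move_interval = 10L, n_walkers = 1L) {
  move_kind <- match.arg(move_kind)
  stopifnot(timestep > 0, friction_gamma > 0, sample_interval >= 1,
            equil_fraction >= 0, equil_fraction < 1,
            lambda_move_interval >= 1, n_walkers >= 1)
  if (is.null(mc_step)) mc_step <- sqrt(2 * timestep / friction_gamma)
  structure(list(timestep = timestep, friction_gamma = friction_gamma,
                 n_steps = as.integer(n_steps),
                 sample_interval = as.integer(sample_interval),
                 seed = seed, move_kind = move_kind, mc_step = mc_step,
                 equil_fraction = equil_fraction,
                 lambda_move_interval = as.integer(lambda_move_interval),
                 n_walkers = as.integer(n_walkers)),
            class = "sampler_settings")
}

move_kind_code <- function(settings) {
  switch(settings$move_kind, langevin = 0L, metropolis = 1L, exact_ou = 2L)
}

#' Single overdamped Langevin step
#'
#' Reference R implementation of the configuration update used by the
#' compiled samplers; useful for unit-level checks and custom loops.
#'
#' @param config a numeric coordinate vector or [configuration()].
#' @param system an `alch_system`.
#' @param lam lambda vector.
#' @param settings a [sampler_settings()].
#' @param thermo a [thermo_params()].
#' @param noise optional fixed noise vector (standard-normal scale); when
#'   NULL, standard normals are drawn from the current RNG stream.
#' @return the updated coordinate vector.
#' @export
langevin_step <- function(config, system, lam, settings = sampler_settings(),
                          thermo = thermo_params(), noise = NULL) {
  x <- as_coords(config)
  g <- system$gradient(x, lam)
  if (!all(is.finite(g))) stop("non-finite force encountered in Langevin step")
  if (is.null(noise)) noise <- rnorm(length(x))
  dt <- settings$timestep
  gam <- settings$friction_gamma
  beta <- as_thermo(thermo)$beta
  x - (dt / gam) * g + sqrt(2 * dt / (beta * gam)) * noise
}

#' Conditional lambda weights of the expanded ensemble
#'
#' Computes `w_lambda = P(lambda | x)` over the bias grid,
#' `w_lambda` proportional to `pi_lambda exp(f_lambda - beta H(x; lambda))`,
#' normalized to sum to one (log-sum-exp shifted, so a constant added to all
#' `f` leaves the weights unchanged).
#'
#' @param config coordinates.
#' @param system an `alch_system` whose lambda grid matches the bias.
#' @param bias an [awh_bias()].
#' @param thermo a [thermo_params()].
#' @return a non-negative weight vector summing to one.
#' @export
lambda_conditional_weights <- function(config, system, bias,
                                       thermo = thermo_params()) {
  x <- as_coords(config)
  beta <- as_thermo(thermo)$beta
  e <- apply(bias$grid, 1L, function(l) system$energy(x, l))
  logw <- log(bias$target) + bias$f - beta * e
  m <- max(logw)
  if (!is.finite(m)) stop("all lambda weights underflowed")
  w <- exp(logw - m)
  w / sum(w)
}

#' Gibbs move in lambda
#'
#' Draws a new lambda-grid index from the full conditional
#' [lambda_conditional_weights()], which satisfies detailed balance with
#' respect to the expanded-ensemble joint distribution at fixed bias.
#'
#' @inheritParams lambda_conditional_weights
#' @return the sampled 1-based lambda index.
#' @export
lambda_gibbs_move <- function(config, system, bias, thermo = thermo_params()) {
  w <- lambda_conditional_weights(config, system, bias, thermo)
  sample.int(length(w), size = 1L, prob = w)
}

#' Force time series
#'
#' Ordered samples of the generalized force `dH/dlambda^mu` at one lambda
#' point, with the sampling interval in time units and an equilibration
#' discard already applied.
#'
#' @param values numeric matrix (samples x lambda components) or vector.
#' @param dt time between retained samples.
#' @param lambda the lambda vector of the series.
#' @param discarded number of equilibration samples that were removed.
#' @return an object of class `force_series`.
#' @export
force_series <- function(values, dt, lambda, discarded = 0L) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("force series must have length >= 2 after discard")
  if (!all(is.finite(values))) stop("force series contains non-finite values")
  structure(list(values = values, dt = dt, lambda = as.numeric(lambda),
                 discarded = as.integer(discarded)),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("force_series: %d samples x %d component(s), dt = %g, lambda = (%s)\n",
              nrow(x$values), ncol(x$values), x$dt,
              paste(signif(x$lambda, 4), collapse = ", ")))
  invisible(x)
}

#' Fixed-lambda sampling over a grid
#'
#' Runs one equilibrated simulation per lambda grid point and collects the
#' generalized-force series needed for the friction / Fisher-Rao metrics and
#' thermodynamic integration, plus the cross-evaluated potential energies
#' needed by BAR/MBAR.
#'
#' @param system an `alch_system`.
#' @param lambda lambda grid: numeric vector (1D) or matrix with one row per
#'   point.
#' @param settings a [sampler_settings()]; `n_steps` applies per point.
#' @param thermo a [thermo_params()].
#' @param store_configs keep the sampled configurations (memory permitting).
#' @return an object of class `fixed_lambda_run` with fields `series` (list
#'   of [force_series()]), `u` (list of reduced-energy matrices, samples x
#'   grid points, of each run evaluated at every grid point), `lambda_grid`,
#'   `beta` and `settings`.
#' @export
run_fixed_lambda <- function(system, lambda, settings = sampler_settings(),
                             thermo = thermo_params(), store_configs = FALSE) {
  grid <- as_lambda_matrix(lambda, system$n_lambda_dims)
  if (nrow(grid) < 1L) stop("lambda grid must be nonempty")
  thermo <- as_thermo(thermo)
  with_seed(settings$seed, {
    series <- vector("list", nrow(grid))
    u <- vector("list", nrow(grid))
    configs <- if (store_configs) vector("list", nrow(grid)) else NULL
    for (i in seq_len(nrow(grid))) {
      res <- tryCatch(
        cpp_run_fixed_lambda(system$kernel_id, system$params, grid,
                             i - 1L, system$x0, settings$n_steps,
                             settings$timestep, settings$friction_gamma,
                             thermo$beta, settings$sample_interval,
                             store_configs, move_kind_code(settings),
                             settings$mc_step),
        error = function(e) stop(sprintf(
          "propagation failed at lambda point %d (%s): %s", i,
          paste(signif(grid[i, ], 4), collapse = ", "), conditionMessage(e)),
          call. = FALSE))
      ndisc <- floor(settings$equil_fraction * nrow(res$dhdl))
      keep <- seq.int(ndisc + 1L, nrow(res$dhdl))
      series[[i]] <- force_series(res$dhdl[keep, , drop = FALSE],
                                  dt = settings$timestep * settings$sample_interval,
                                  lambda = grid[i, ], discarded = ndisc)
      u[[i]] <- thermo$beta * res$u_grid[keep, , drop = FALSE]
      if (store_configs) configs[[i]] <- res$configs[keep, , drop = FALSE]
    }
    structure(list(series = series, u = u, configs = configs,
                   lambda_grid = grid, beta = thermo$beta,
                   settings = settings),
              class = "fixed_lambda_run")
  })
}

#' @export
print.fixed_lambda_run <- function(x, ...) {
  cat(sprintf("fixed_lambda_run: %d lambda points, %d samples each\n",
              nrow(x$lambda_grid), nrow(x$series[[1]]$values)))
  invisible(x)
}

#' Expanded-ensemble run with an adaptive weight-histogram bias
#'
#' Alternates blocks of configuration moves with full-grid Gibbs lambda
#' moves, feeding the accumulated conditional weights to the adaptive bias
#' between epochs. One epoch spans `bias$update_interval` lambda moves and
#' ends with one bias update. Multiple communicating walkers (sequentially
#' executed) can share the same bias.
#'
#' @param system an `alch_system`.
#' @param bias an [awh_bias()] initialized on the system's lambda grid.
#' @param settings a [sampler_settings()].
#' @param thermo a [thermo_params()].
#' @param n_updates number of bias updates (epochs) to perform.
#' @param record store per-sample conditional weights and grid-wide
#'   generalized forces (needed by [diffusion_metric()]).
#' @param dynamic_target when TRUE, re-optimize the target distribution from
#'   the on-the-fly diffusion metric after each update once the bias has
#'   left the initial stage (see [awh_dynamic_target()]).
#' @param metric_half_life half-life, in bias updates, of the exponential
#'   forgetting applied to the on-the-fly metric accumulation.
#' @return a list with components `trajectory` (class `ee_trajectory`:
#'   weight matrix `w`, array `dhdl_grid` of forces at every grid point,
#'   lambda index trace, visit counts, sample spacing `dt`) and `bias` (the
#'   final [awh_bias()], including the update-by-update free-energy trace).
#' @export
run_expanded_ensemble <- function(system, bias, settings = sampler_settings(),
                                  thermo = thermo_params(), n_updates = 100L,
                                  record = TRUE, dynamic_target = FALSE,
                                  metric_half_life = 10) {
  stopifnot(inherits(bias, "awh_bias"))
  grid <- bias$grid
  stopifnot(ncol(grid) == system$n_lambda_dims)
  thermo <- as_thermo(thermo)
  np <- nrow(grid)
  nl <- ncol(grid)
  with_seed(settings$seed, {
    nw <- settings$n_walkers
    xw <- replicate(nw, system$x0, simplify = FALSE)
    iw <- rep(1L, nw)
    w_chunks <- list()
    dh_chunks <- list()
    il_chunks <- list()
    xs_chunks <- list()
    gbar <- NULL   # on-the-fly diffusion-metric accumulator
    decay <- 2^(-1 / metric_half_life)
    record_epoch <- record || dynamic_target
    for (u in seq_len(n_updates)) {
      epoch_w <- NULL
      epoch_dh <- NULL
      for (k in seq_len(nw)) {
        res <- cpp_run_ee_epoch(system$kernel_id, system$params, grid,
                                bias$f, bias$target, thermo$beta, xw[[k]],
                                iw[k] - 1L, bias$update_interval,
                                settings$lambda_move_interval,
                                settings$timestep, settings$friction_gamma,
                                settings$sample_interval, record_epoch,
                                move_kind_code(settings), settings$mc_step)
        bias <- awh_accumulate(bias, res$whist, n = res$n_moves)
        bias$visits <- bias$visits + res$visits
        xw[[k]] <- res$x_final
        iw[k] <- res$ilam_final
        if (record_epoch && res$n_recorded > 0) {
          keep <- seq_len(res$n_recorded)
          if (record) {
            w_chunks[[length(w_chunks) + 1L]] <- res$w_samples[keep, , drop = FALSE]
            dh_chunks[[length(dh_chunks) + 1L]] <- res$dhdl_grid[keep, , drop = FALSE]
            il_chunks[[length(il_chunks) + 1L]] <- res$ilam_trace[keep]
            xs_chunks[[length(xs_chunks) + 1L]] <- res$xtrace[keep]
          }
          epoch_w <- rbind(epoch_w, res$w_samples[keep, , drop = FALSE])
          epoch_dh <- rbind(epoch_dh, res$dhdl_grid[keep, , drop = FALSE])
        }
      }
      bias <- awh_update(bias)
      if (dynamic_target && bias$stage == "final" && !is.null(epoch_w) &&
          nrow(epoch_w) >= 20L) {
        gk <- onfly_metric_chunk(epoch_w, epoch_dh, np, nl,
                                 dt = settings$timestep *
                                   settings$lambda_move_interval *
                                   settings$sample_interval)
        gbar <- if (is.null(gbar)) gk else decay * gbar + (1 - decay) * gk
        met <- metric_estimate(grid, value = pmax(gbar, 0),
                               se = rep(NA_real_, np), estimator = "diffusion")
        bias <- awh_dynamic_target(bias, met)
      }
    }
    dt_sample <- settings$timestep * settings$lambda_move_interval *
      settings$sample_interval
    traj <- structure(list(
      w = if (record) do.call(rbind, w_chunks) else NULL,
      dhdl_grid = if (record) do.call(rbind, dh_chunks) else NULL,
      ilam = if (record) unlist(il_chunks) else NULL,
      x_summary = if (record) unlist(xs_chunks) else NULL,
      lambda_grid = grid, n_lambda_dims = nl, beta = thermo$beta,
      dt = dt_sample, visits = bias$visits),
      class = "ee_trajectory")
    list(trajectory = traj, bias = bias)
  })
}

# quick per-epoch diffusion-metric estimate for on-the-fly target updates:
# integrated correlation of dF*w per point with the automatic window rule,
# on one epoch of data (scalar lambda per dimension summed into det form)
onfly_metric_chunk <- function(w, dh, np, nl, dt) {
  vapply(seq_len(np), function(j) {
    wj <- w[, j]
    m2 <- mean(wj^2)
    if (m2 <= 0) return(NA_real_)
    det_comp <- 1
    for (k in seq_len(nl)) {
      fj <- dh[, j + (k - 1) * np]
      mu <- sum(wj * fj) / max(sum(wj), .Machine$double.eps)
      u <- (fj - mu) * wj
      val <- tryCatch(integrated_correlation(u, dt = dt, min_len = 20L),
                      error = function(e) NA_real_)
      det_comp <- det_comp * max(as.numeric(val), 0) / m2
    }
    det_comp
  }, numeric(1))
}
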