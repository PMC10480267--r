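#' Free energy result
#'
#' @param dG free energy difference (energy units).
#' @param se standard error (>= 0 or NA).
#' @param method method tag (`"ti"`, `"bar"`, `"mbar"`, `"awh"`, ...).
#' @param breakdown optional per-leg breakdown or extra diagnostics.
#' @return an object of class `free_energy_result`.
#' @export
free_energy_result <- function(dG, se = NA_real_, method = "unknown",
                               breakdown = NULL) {
  if (!is.na(se) && se < 0) stop("standard error must be >= 0")
  structure(list(dG = dG, se = se, method = method, breakdown = breakdown),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("dG = %.6g +/- %.3g (%s)\n", x$dG,
              if (is.na(x$se)) NA else x$se, x$method))
  invisible(x)
}

#' Thermodynamic integration with the trapezoidal rule
#'
#' \eqn{G_B - G_A = \int_0^1 \langle \partial H/\partial\lambda
#'   \rangle_\lambda d\lambda} by trapezoidal quadrature of the per-point
#' mean gradients. Standard errors are propagated from per-point standard
#' errors assuming independence between lambda points. A reversed grid
#' negates the result.
#'
#' @param means per-point mean gradients, or a [run_fixed_lambda()] result
#'   (1D) whose per-point means and standard errors are computed from the
#'   stored force series.
#' @param lambda lambda grid values (required when `means` is numeric).
#' @param se optional per-point standard errors of the means.
#' @return a [free_energy_result()] with method `"ti"`.
#' @export
ti_trapezoid <- function(means, lambda = NULL, se = NULL) {
  if (inherits(means, "fixed_lambda_run")) {
    run <- means
    stopifnot(ncol(run$lambda_grid) == 1L)
    lambda <- run$lambda_grid[, 1L]
    stats <- lapply(run$series, function(fs) series_mean_se(fs$values[, 1L]))
    means <- vapply(stats, `[[`, numeric(1), "mean")
    se <- vapply(stats, `[[`, numeric(1), "se")
  }
  stopifnot(length(means) == length(lambda), length(lambda) >= 2L)
  dl <- diff(lambda)
  w <- c(dl / 2, 0) + c(0, dl / 2)  # trapezoid weights per point
  dG <- sum(w * means)
  se_out <- if (is.null(se)) NA_real_ else sqrt(sum((w * se)^2))
  free_energy_result(dG, se_out, method = "ti",
                     breakdown = list(lambda = lambda, means = means))
}

# mean and autocorrelation-aware standard error of a scalar series
series_mean_se <- function(x, n_blocks = 10L) {
  nb <- min(n_blocks, max(2L, length(x) %/% 20L))
  blocks <- split(x, cut(seq_along(x), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  list(mean = mean(x), se = sd(bm) / sqrt(length(bm)))
}

#' Bennett acceptance ratio for one pair of states
#'
#' Solves the Bennett self-consistency equation for `beta dG` by bracketed
#' root finding (tolerance 1e-10): with `M = log(N_F/N_R)` and reduced
#' works `w_F = beta(U_B - U_A)` on A-samples, `w_R = beta(U_A - U_B)` on
#' B-samples, the root `C` of
#' \deqn{\sum_F \frac{1}{1 + e^{M + w_F - C}} =
#'       \sum_R \frac{1}{1 + e^{-M + w_R + C}}}
#' gives `dG = C / beta`. The asymptotic standard error uses the standard
#' Fermi-function variance expression. When the two work distributions do
#' not overlap (all Fermi terms saturated), a warning is issued and the
#' standard error flagged unreliable.
#'
#' @param w_forward forward reduced work samples `beta dU` from state A.
#' @param w_reverse reverse reduced work samples from state B.
#' @param thermo a [thermo_params()] used to convert to energy units.
#' @return a [free_energy_result()] with method `"bar"`; `breakdown`
#'   carries `C` (= beta dG) and the overlap flag.
#' @export
bar_pair <- function(w_forward, w_reverse, thermo = thermo_params()) {
  wf <- as.numeric(w_forward); wr <- as.numeric(w_reverse)
  if (length(wf) == 0 || length(wr) == 0)
    stop("both forward and reverse sample sets must be nonempty")
  beta <- as_thermo(thermo)$beta
  M <- log(length(wf) / length(wr))
  fun <- function(C) sum(plogis(-(M + wf - C))) - sum(plogis(-(-M + wr + C)))
  c0 <- (mean(wf) - mean(wr)) / 2
  lo <- c0 - 1; hi <- c0 + 1
  for (k in 1:200) {
    if (fun(lo) < 0 && fun(hi) > 0) break
    width <- (hi - lo)
    if (fun(lo) >= 0) lo <- lo - width
    if (fun(hi) <= 0) hi <- hi + width
  }
  C <- uniroot(fun, c(lo, hi), tol = 1e-10)$root
  af <- plogis(-(M + wf - C))
  ar <- plogis(-(-M + wr + C))
  overlap_ok <- mean(af) > 1e-10 && mean(ar) > 1e-10 &&
    mean(af) < 1 - 1e-10 && mean(ar) < 1 - 1e-10
  if (!overlap_ok)
    warning("poor overlap between forward and reverse work distributions; ",
            "BAR standard error unreliable")
  var_C <- (mean(af^2) / mean(af)^2 - 1) / length(af) +
    (mean(ar^2) / mean(ar)^2 - 1) / length(ar)
  free_energy_result(C / beta, sqrt(max(var_C, 0)) / beta, method = "bar",
                     breakdown = list(C = C, overlap_ok = overlap_ok))
}

#' Reduced energy differences between adjacent lambda points
#'
#' Assembles, from a [run_fixed_lambda()] result, the forward and reverse
#' reduced work samples for every adjacent pair of lambda points (state-k
#' samples re-evaluated at state k+1 and vice versa), as needed by
#' [bar_chain()].
#'
#' @param run a [run_fixed_lambda()] result.
#' @return an object of class `energy_diff_set`: lists `forward` and
#'   `reverse` of length K-1, and sample counts `N_k`.
#' @export
energy_differences <- function(run) {
  stopifnot(inherits(run, "fixed_lambda_run"))
  K <- nrow(run$lambda_grid)
  fw <- vector("list", max(K - 1L, 0L))
  rv <- vector("list", max(K - 1L, 0L))
  for (k in seq_len(K - 1L)) {
    fw[[k]] <- run$u[[k]][, k + 1L] - run$u[[k]][, k]
    rv[[k]] <- run$u[[k + 1L]][, k] - run$u[[k + 1L]][, k + 1L]
  }
  structure(list(forward = fw, reverse = rv,
                 N_k = vapply(run$u, nrow, integer(1))),
            class = "energy_diff_set")
}

#' BAR chain over adjacent lambda pairs
#'
#' Sums [bar_pair()] legs over adjacent lambda points; leg standard errors
#' combine in quadrature. The total is invariant to the leg order.
#'
#' @param x an `energy_diff_set` (see [energy_differences()]) or a
#'   [run_fixed_lambda()] result.
#' @param thermo a [thermo_params()].
#' @return a [free_energy_result()] with method `"bar"` and per-leg
#'   breakdown.
#' @export
bar_chain <- function(x, thermo = thermo_params()) {
  eds <- if (inherits(x, "fixed_lambda_run")) energy_differences(x) else x
  stopifnot(inherits(eds, "energy_diff_set"))
  legs <- lapply(seq_along(eds$forward), function(k)
    bar_pair(eds$forward[[k]], eds$reverse[[k]], thermo))
  dG <- sum(vapply(legs, `[[`, numeric(1), "dG"))
  se <- sqrt(sum(vapply(legs, `[[`, numeric(1), "se")^2))
  free_energy_result(dG, se, method = "bar",
                     breakdown = list(legs = legs))
}

#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Self-consistent solution of the MBAR equations for the reduced free
#' energies `f_k` of all states from the reduced energies `u_kn` of every
#' sample evaluated at every state: damped fixed-point iteration followed
#' by Newton polish, gauge `f_1 = 0`, converged when `max |df| < tol`.
#' Standard errors come from the asymptotic covariance (pseudo-inverse of
#' the MBAR information matrix). With K = 2 states MBAR is identical to
#' BAR.
#'
#' @param u_kn reduced energy matrix (K states x N total samples):
#'   `u_kn[k, n] = beta U_k(x_n)`; samples are ordered by origin state.
#' @param N_k sample counts per state (sums to N).
#' @param thermo a [thermo_params()] for unit conversion of the headline
#'   result.
#' @param tol convergence tolerance on `max |df|` (default 1e-10).
#' @param max_iter maximum iterations before aborting with a residual
#'   report.
#' @return an object of class `mbar_result` with `f` (reduced free
#'   energies, `f[1] = 0`), `Theta` (asymptotic covariance), `se_dG`,
#'   `result` (a [free_energy_result()] for state K vs state 1),
#'   `n_iter`.
#' @export
mbar_solve <- function(u_kn, N_k, thermo = thermo_params(), tol = 1e-10,
                       max_iter = 2000L) {
  u_kn <- as.matrix(u_kn)
  K <- nrow(u_kn); N <- ncol(u_kn)
  stopifnot(length(N_k) == K, sum(N_k) == N, all(N_k > 0),
            all(is.finite(u_kn)))
  beta <- as_thermo(thermo)$beta
  logN <- log(N_k)
  f <- rep(0, K)
  col_max <- function(m) {          # max over states for every sample
    mx <- m[1L, ]
    for (k in seq_len(nrow(m))[-1L]) mx <- pmax(mx, m[k, ])
    mx
  }
  obj_denom <- function(f) {        # log sum_k N_k exp(f_k - u_kn), length N
    m <- (logN + f) - u_kn
    mx <- col_max(m)
    mx + log(colSums(exp(m - rep(mx, each = K))))
  }
  row_lse <- function(m) {          # log sum over samples for every state
    vapply(seq_len(nrow(m)), function(k) {
      mx <- max(m[k, ]); mx + log(sum(exp(m[k, ] - mx)))
    }, numeric(1))
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- obj_denom(f)
    # self-consistent update: f_k = -log sum_n exp(-u_kn - d_n)
    fnew <- -row_lse(-u_kn - rep(d, each = K))
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < 1e-6 || iter >= 50L) break
  }
  # Newton polish on the reduced coordinates (f_2, ..., f_K)
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- obj_denom(f)
    logW <- sweep(f - u_kn, 2L, d)          # K x N, log W~_nk
    W <- exp(logW)
    gvec <- N_k * (rowSums(W) - 1)
    H <- -(W * N_k) %*% t(W * N_k)
    diag(H) <- diag(H) + N_k * rowSums(W)
    step <- tryCatch(solve(H[-1L, -1L, drop = FALSE], gvec[-1L]),
                     error = function(e) gvec[-1L] / pmax(diag(H)[-1L], 1))
    if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))  # damping
    fnew <- f
    fnew[-1L] <- f[-1L] - step
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  if (iter >= max_iter) {
    d <- obj_denom(f)
    W <- exp(sweep(f - u_kn, 2L, d))
    stop(sprintf(
      "MBAR did not converge in %d iterations (max residual %.3g)",
      max_iter, max(abs(N_k * (rowSums(W) - 1)))))
  }
  d <- obj_denom(f)
  W <- exp(sweep(f - u_kn, 2L, d))   # K x N, W[k, n] = exp(f_k - u_kn - d_n)
  # asymptotic covariance Theta = V S (I - S V' diag(N) V S)^+ S V'
  # from the spectral decomposition W W' = V S^2 V' (sample-weight form)
  A <- tcrossprod(W)                  # K x K, equals (W')'(W') over samples
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  s <- sqrt(pmax(eg$values, 0))
  V <- eg$vectors
  M <- diag(K) - (s * t(V)) %*% (N_k * V) %*% diag(s, K)
  egm <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- egm$values > max(abs(egm$values)) * 1e-10
  Minv <- egm$vectors[, pos, drop = FALSE] %*%
    diag(1 / egm$values[pos], sum(pos)) %*%
    t(egm$vectors[, pos, drop = FALSE])
  Theta <- V %*% diag(s, K) %*% Minv %*% diag(s, K) %*% t(V)
  se_dG <- sqrt(max(Theta[1, 1] + Theta[K, K] - 2 * Theta[1, K], 0))
  structure(list(f = f, Theta = Theta, se_dG = se_dG / beta,
                 result = free_energy_result((f[K] - f[1L]) / beta,
                                             se_dG / beta, method = "mbar"),
                 n_iter = iter),
            class = "mbar_result")
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("mbar_result: %d states, dG = %.6g +/- %.3g (%d iterations)\n",
              length(x$f), x$result$dG, x$result$se, x$n_iter))
  invisible(x)
}

#' Assemble the MBAR input from a fixed-lambda run
#'
#' Stacks the per-run reduced energies evaluated at every grid point into
#' the `u_kn` matrix expected by [mbar_solve()].
#'
#' @param run a [run_fixed_lambda()] result.
#' @return a list with `u_kn` and `N_k`.
#' @export
mbar_input <- function(run) {
  stopifnot(inherits(run, "fixed_lambda_run"))
  u_kn <- t(do.call(rbind, run$u))
  list(u_kn = u_kn, N_k = vapply(run$u, nrow, integer(1)))
}

#' Root mean square error over repeated estimates
#'
#' `sqrt(mean((estimate - reference)^2))`; the reference defaults to the
#' pooled mean of the estimates, mirroring repeat-evaluation protocols that
#' measure deviations from the average over all simulations.
#'
#' @param estimates numeric vector of repeated estimates.
#' @param reference reference value (default: `mean(estimates)`).
#' @return the RMSE (>= 0).
#' @export
rmse_over_repeats <- function(estimates, reference = mean(estimates)) {
  sqrt(mean((estimates - reference)^2))
}

#' One-sigma bootstrap interval of a statistic
#'
#' Percentile interval at the one-sigma quantiles (15.87%, 84.13%) of the
#' bootstrap distribution of `statistic` over resamples of `values`;
#' 5000 bootstrap samples by default.
#'
#' @param values sample values to resample.
#' @param statistic function of a numeric vector (default `mean`; use e.g.
#'   `function(x) rmse_over_repeats(x, ref)` for an RMSE interval).
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for reproducibility (NULL: current stream).
#' @return a list with `lower`, `upper`, `se` (half-width) and `estimate`.
#' @export
bootstrap_sigma <- function(values, statistic = mean, n_boot = 5000L,
                            seed = NULL) {
  values <- as.numeric(values)
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i)
      statistic(values[sample.int(length(values), replace = TRUE)]),
      numeric(1))
    qs <- quantile(boots, c(0.1587, 0.8413), names = FALSE, type = 7)
    list(lower = qs[1], upper = qs[2], se = (qs[2] - qs[1]) / 2,
         estimate = statistic(values))
  })
}

#' Empirical improvement factor from measured errors
#'
#' `(rmse_optimized / rmse_reference)^2`: because the statistical error
#' decays as `1/sqrt(time)` after equilibration, the squared RMSE ratio is
#' the measured reduction in computational time achieved by the optimized
#' protocol.
#'
#' @param rmse_optimized RMSE of the optimized protocol.
#' @param rmse_reference RMSE of the reference (unoptimized) protocol.
#' @return the empirical improvement factor (> 0; < 1 means the optimized
#'   protocol is more efficient).
#' @export
empirical_improvement_factor <- function(rmse_optimized, rmse_reference) {
  stopifnot(rmse_optimized >= 0, rmse_reference > 0)
  (rmse_optimized / rmse_reference)^2
}

#' Repeat-evaluation report
#'
#' Summarizes repeated free-energy estimates: RMSE against a reference
#' (pooled mean by default) with a one-sigma bootstrap interval.
#'
#' @param estimates numeric vector of repeated estimates.
#' @param reference reference value; default pooled mean.
#' @param n_boot bootstrap samples for the RMSE interval.
#' @param seed bootstrap seed.
#' @return an object of class `eval_report` with `rmse`, `ci`
#'   (list lower/upper/se), `reference`, `n_repeats`.
#' @export
eval_report <- function(estimates, reference = NULL, n_boot = 5000L,
                        seed = NULL) {
  estimates <- as.numeric(estimates)
  ref <- reference %||% mean(estimates)
  ci <- bootstrap_sigma(estimates,
                        statistic = function(x) rmse_over_repeats(x, ref),
                        n_boot = n_boot, seed = seed)
  structure(list(rmse = rmse_over_repeats(estimates, ref), ci = ci,
                 reference = ref, n_repeats = length(estimates)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: RMSE = %.4g (one-sigma %.4g..%.4g) over %d repeats\n",
              x$rmse, x$ci$lower, x$ci$upper, x$n_repeats))
  invisible(x)
}
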