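#' Metric estimate container
#'
#' A metric profile over a lambda grid: a scalar `g(lambda)` per point in
#' one lambda dimension, or a symmetric 2x2 tensor `g_munu` per point in
#' two. Tensors are stored as an array `(n_points, ndim, ndim)`; after
#' clipping, scalar values are non-negative and tensor eigenvalues are >= 0.
#'
#' @param lambda lambda grid (vector or matrix, one row per point).
#' @param value numeric vector (scalar metric) or array
#'   `(n_points, ndim, ndim)`.
#' @param se standard errors, same shape as `value`.
#' @param estimator one of `"friction"`, `"diffusion"`, `"fisher_rao"`.
#' @param window window parameters used by the estimator (free-form list).
#' @param clipped number of points whose value was clipped to keep the
#'   metric positive semi-definite.
#' @param interpolated logical vector flagging grid points whose value was
#'   filled in by interpolation.
#' @return an object of class `metric_estimate`.
#' @export
metric_estimate <- function(lambda, value, se = NULL,
                            estimator = c("friction", "diffusion",
                                          "fisher_rao"),
                            window = list(), clipped = 0L,
                            interpolated = NULL) {
  estimator <- match.arg(estimator)
  grid <- if (is.matrix(lambda)) lambda else matrix(as.numeric(lambda), ncol = 1L)
  np <- nrow(grid)
  if (is.array(value) && length(dim(value)) == 3L) {
    stopifnot(dim(value)[1] == np)
  } else {
    value <- as.numeric(value)
    stopifnot(length(value) == np)
    if (any(value < 0, na.rm = TRUE)) stop("scalar metric values must be >= 0")
  }
  structure(list(lambda = grid, value = value, se = se,
                 estimator = estimator, window = window,
                 clipped = as.integer(clipped),
                 interpolated = interpolated %||% rep(FALSE, np)),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  kind <- if (is.array(x$value) && length(dim(x$value)) == 3L) "tensor" else "scalar"
  cat(sprintf("metric_estimate (%s): %s over %d lambda points (%d clipped)\n",
              x$estimator, kind, nrow(x$lambda), x$clipped))
  invisible(x)
}

is_tensor_metric <- function(m) is.array(m$value) && length(dim(m$value)) == 3L

# sqrt(det g) per grid point; in 1D det g = g
sqrt_det_metric <- function(metric) {
  if (!is_tensor_metric(metric)) return(sqrt(pmax(metric$value, 0)))
  apply(metric$value, 1L, function(g) sqrt(max(det(g), 0)))
}

#' Integrated time-correlation of two sample series
#'
#' Estimates \eqn{\int_0^\infty \langle \delta a(t)\,\delta b(0)\rangle dt}
#' from equally spaced samples by the discrete sum
#' `dt * (C_0/2 + sum_{k=1..W} C_k)`, with mean-subtracted (cross-)
#' correlations symmetrized in the two series. The automatic window rule
#' picks the smallest `W >= 5 * tau_int(W)` (self-consistent integrated
#' autocorrelation time, in samples), capped at a tenth of the series
#' length.
#'
#' @param a,b numeric sample series of equal length (`b` defaults to `a`).
#' @param dt time between samples.
#' @param window `"auto"` or a fixed integer window.
#' @param min_len minimum admissible series length (default 50).
#' @return the integrated correlation (units value^2 x time), with
#'   attributes `window` and `tau_int`.
#' @export
integrated_correlation <- function(a, b = a, dt = 1, window = "auto",
                                   min_len = 50L) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("series lengths differ")
  if (n < min_len)
    stop(sprintf("series too short (%d < %d): sample longer", n, min_len))
  da <- a - mean(a); db <- b - mean(b)
  wcap <- max(1L, n %/% 10L)
  # biased (1/n) cross-correlations up to the cap, symmetrized
  cc <- crosscorr_fft(da, db, wcap)
  if (identical(window, "auto")) {
    W <- auto_window(autocorr_rho(da, wcap), wcap)
    if (!identical(a, b)) W <- max(W, auto_window(autocorr_rho(db, wcap), wcap))
  } else {
    W <- min(as.integer(window), wcap)
  }
  val <- dt * (cc[1L] / 2 + sum(cc[seq_len(W) + 1L]))
  structure(val, window = W, tau_int = (0.5 + sum(cc[seq_len(W) + 1L]) /
                                          max(cc[1L], .Machine$double.eps)))
}

# symmetrized cross-correlation C_k = (<da_{t+k} db_t> + <db_{t+k} da_t>)/2,
# k = 0..wcap, normalized by n (biased form), computed via FFT
crosscorr_fft <- function(da, db, wcap) {
  n <- length(da)
  m <- 2^ceiling(log2(2 * n))
  fa <- fft(c(da, rep(0, m - n)))
  fb <- fft(c(db, rep(0, m - n)))
  cc_ab <- Re(fft(fa * Conj(fb), inverse = TRUE)) / m
  cc_ba <- Re(fft(fb * Conj(fa), inverse = TRUE)) / m
  idx <- seq_len(wcap + 1L)
  (cc_ab[idx] + cc_ba[idx]) / (2 * n)
}

autocorr_rho <- function(d, wcap) {
  cc <- crosscorr_fft(d, d, wcap)
  cc / max(cc[1L], .Machine$double.eps)
}

# smallest W with W >= 5 * tau_int(W), tau_int(W) = 1/2 + sum_{k<=W} rho_k
auto_window <- function(rho, wcap) {
  tau <- 0.5
  for (W in seq_len(wcap)) {
    tau <- tau + rho[W + 1L]
    if (W >= 5 * tau) return(W)
  }
  wcap
}

# generic per-point estimator with delete-one-block jackknife errors.
# fun(values_matrix, dt) -> ndim x ndim matrix (or scalar for ndim = 1)
per_point_blocked <- function(series_list, fun, n_blocks = 10L) {
  lapply(series_list, function(fs) {
    v <- fs$values
    n <- nrow(v)
    full <- fun(v, fs$dt)
    nb <- min(n_blocks, max(2L, n %/% 50L))
    bounds <- floor(seq(0, n, length.out = nb + 1L))
    jk <- lapply(seq_len(nb), function(i) {
      keep <- setdiff(seq_len(n), seq.int(bounds[i] + 1L, bounds[i + 1L]))
      fun(v[keep, , drop = FALSE], fs$dt)
    })
    jbar <- Reduce(`+`, jk) / nb
    jse <- sqrt((nb - 1) / nb *
                  Reduce(`+`, lapply(jk, function(t) (t - jbar)^2)))
    list(value = full, se = jse)
  })
}

series_from_run <- function(x) {
  if (inherits(x, "fixed_lambda_run")) return(x$series)
  if (inherits(x, "force_series")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "force_series")))
    return(x)
  stop("expected a fixed_lambda_run or a list of force_series")
}

assemble_metric <- function(series_list, pp, estimator, window, clip_tol = 0) {
  grid <- do.call(rbind, lapply(series_list, function(s) s$lambda))
  nl <- ncol(series_list[[1]]$values)
  clipped <- 0L
  if (nl == 1L) {
    val <- vapply(pp, function(e) as.numeric(e$value), numeric(1))
    se <- vapply(pp, function(e) as.numeric(e$se), numeric(1))
    neg <- val < 0
    clipped <- sum(neg)
    val[neg] <- 0
  } else {
    np <- length(pp)
    val <- array(NA_real_, c(np, nl, nl))
    se <- array(NA_real_, c(np, nl, nl))
    for (i in seq_len(np)) {
      g <- (pp[[i]]$value + t(pp[[i]]$value)) / 2
      eg <- eigen(g, symmetric = TRUE)
      if (any(eg$values < -abs(clip_tol))) clipped <- clipped + 1L
      ev <- pmax(eg$values, 0)
      val[i, , ] <- eg$vectors %*% diag(ev, nl) %*% t(eg$vectors)
      se[i, , ] <- pp[[i]]$se
    }
  }
  metric_estimate(grid, val, se, estimator = estimator, window = window,
                  clipped = clipped)
}

#' Friction metric from fixed-lambda force series
#'
#' The integrated time-autocorrelation of the generalized force at each
#' lambda point,
#' \eqn{g_{\mu\nu}(\lambda) = \int_0^\infty
#'   \langle \delta F_\mu(t) \delta F_\nu(0)\rangle_\lambda dt.}
#' This metric doubles as the friction tensor of slowly driven
#' non-equilibrium protocols. Standard errors are delete-one-block
#' jackknife estimates.
#'
#' @param x a [run_fixed_lambda()] result or a list of [force_series()].
#' @param window `"auto"` or a fixed integer window.
#' @param n_blocks number of jackknife blocks.
#' @return a [metric_estimate()] with estimator `"friction"`.
#' @export
friction_metric <- function(x, window = "auto", n_blocks = 10L) {
  series <- series_from_run(x)
  fun <- function(v, dt) {
    nl <- ncol(v)
    if (nl == 1L)
      return(as.numeric(integrated_correlation(v[, 1L], dt = dt,
                                               window = window)))
    g <- matrix(0, nl, nl)
    for (i in seq_len(nl)) for (j in i:nl) {
      g[i, j] <- g[j, i] <-
        as.numeric(integrated_correlation(v[, i], v[, j], dt = dt,
                                          window = window))
    }
    g
  }
  pp <- per_point_blocked(series, fun, n_blocks)
  assemble_metric(series, pp, "friction", list(rule = window))
}

#' Fisher-Rao (equal-time) metric
#'
#' The per-point equal-time covariance of the generalized force,
#' \eqn{\langle \delta F_\mu \delta F_\nu \rangle_\lambda}. It ignores time
#' correlations, which is exactly why comparing it with the friction metric
#' is informative.
#'
#' @inheritParams friction_metric
#' @return a [metric_estimate()] with estimator `"fisher_rao"`.
#' @export
fisher_rao_metric <- function(x, n_blocks = 10L) {
  series <- series_from_run(x)
  fun <- function(v, dt) {
    nl <- ncol(v)
    if (nl == 1L) return(mean((v[, 1L] - mean(v[, 1L]))^2))
    cv <- cov(v) * (nrow(v) - 1) / nrow(v)
    (cv + t(cv)) / 2
  }
  pp <- per_point_blocked(series, fun, n_blocks)
  assemble_metric(series, pp, "fisher_rao", list())
}

#' Diffusion metric from an expanded-ensemble trajectory
#'
#' For each lambda grid point,
#' \eqn{g_{\mu\nu}(\lambda) = \int_0^\infty
#'   \langle \delta F_\mu(t) w_\lambda(t) \delta F_\nu(0) w_\lambda(0)\rangle
#'   / \langle w_\lambda^2\rangle \, dt,}
#' where `w_lambda(t) = P(lambda | x(t))` are the conditional weights
#' recorded along the trajectory and `delta F` subtracts the
#' weight-weighted mean of the force at that point. On a single-point grid
#' (`w == 1`) this reduces to the friction metric.
#'
#' @param traj an `ee_trajectory` from [run_expanded_ensemble()] run with
#'   `record = TRUE`.
#' @param window `"auto"` or a fixed integer window.
#' @param interpolate fill never-visited points (`<w^2> = 0`) by
#'   log-linear interpolation across the grid (1D only); otherwise they are
#'   reported as `NA`.
#' @return a [metric_estimate()] with estimator `"diffusion"`.
#' @export
diffusion_metric <- function(traj, window = "auto", interpolate = FALSE) {
  stopifnot(inherits(traj, "ee_trajectory"))
  if (is.null(traj$w)) stop("trajectory was recorded without weights")
  np <- nrow(traj$lambda_grid)
  nl <- traj$n_lambda_dims
  val_list <- vector("list", np)
  missing <- rep(FALSE, np)
  for (jp in seq_len(np)) {
    wj <- traj$w[, jp]
    m2 <- mean(wj^2)
    if (!is.finite(m2) || m2 <= 0) { missing[jp] <- TRUE; next }
    u <- matrix(0, nrow(traj$w), nl)
    for (k in seq_len(nl)) {
      fj <- traj$dhdl_grid[, jp + (k - 1) * np]
      mu <- sum(wj * fj) / sum(wj)
      u[, k] <- (fj - mu) * wj
    }
    g <- matrix(0, nl, nl)
    for (i in seq_len(nl)) for (j2 in i:nl) {
      g[i, j2] <- g[j2, i] <-
        as.numeric(integrated_correlation(u[, i], u[, j2], dt = traj$dt,
                                          window = window)) / m2
    }
    val_list[[jp]] <- g
  }
  clipped <- 0L
  if (nl == 1L) {
    val <- vapply(seq_len(np), function(i)
      if (missing[i]) NA_real_ else val_list[[i]][1, 1], numeric(1))
    clipped <- sum(val < 0, na.rm = TRUE)
    val[!is.na(val) & val < 0] <- 0
    interp <- rep(FALSE, np)
    if (interpolate && any(missing) && !all(missing)) {
      lam <- traj$lambda_grid[, 1L]
      ok <- !missing & val > 0
      fill <- missing | val <= 0
      if (sum(ok) >= 2L) {
        val[fill] <- exp(approx(lam[ok], log(val[ok]), xout = lam[fill],
                                rule = 2)$y)
        interp[fill] <- TRUE
      }
    }
    met <- metric_estimate(traj$lambda_grid, pmax(val, 0),
                           se = rep(NA_real_, np), estimator = "diffusion",
                           window = list(rule = window), clipped = clipped,
                           interpolated = interp)
  } else {
    arr <- array(NA_real_, c(np, nl, nl))
    for (i in seq_len(np)) {
      if (missing[i]) next
      g <- val_list[[i]]
      eg <- eigen(g, symmetric = TRUE)
      if (any(eg$values < 0)) clipped <- clipped + 1L
      arr[i, , ] <- eg$vectors %*% diag(pmax(eg$values, 0), nl) %*%
        t(eg$vectors)
    }
    met <- metric_estimate(traj$lambda_grid, arr, se = NULL,
                           estimator = "diffusion",
                           window = list(rule = window), clipped = clipped,
                           interpolated = missing)
  }
  met
}

#' Metric tensor field on a 2D lambda grid
#'
#' Estimates the 2x2 metric tensor at every node of a rectangular
#' `lambda_1 x lambda_2` grid (friction estimator on fixed-lambda runs, or
#' diffusion estimator on an expanded-ensemble trajectory), and derives the
#' scalar `sqrt(det g)` field used for target and path optimization.
#'
#' @param x a [run_fixed_lambda()] result or `ee_trajectory` whose lambda
#'   grid is a full rectangular 2D grid.
#' @param ... passed to [friction_metric()] / [diffusion_metric()].
#' @return an object of class `metric_field`: `l1`, `l2` (axis values), `g`
#'   (array `n1 x n2 x 2 x 2`), `sqrt_det` (matrix `n1 x n2`), and the
#'   underlying [metric_estimate()].
#' @export
metric_field_2d <- function(x, ...) {
  met <- if (inherits(x, "ee_trajectory")) diffusion_metric(x, ...)
         else friction_metric(x, ...)
  metric_field_from_estimate(met)
}

#' Arrange a per-point tensor metric estimate on its rectangular grid
#'
#' @param met a [metric_estimate()] with 2D lambda grid covering all
#'   combinations of its axis values.
#' @return a `metric_field` (see [metric_field_2d()]).
#' @export
metric_field_from_estimate <- function(met) {
  stopifnot(inherits(met, "metric_estimate"))
  grid <- met$lambda
  stopifnot(ncol(grid) == 2L)
  l1 <- sort(unique(grid[, 1L]))
  l2 <- sort(unique(grid[, 2L]))
  n1 <- length(l1); n2 <- length(l2)
  if (n1 * n2 != nrow(grid))
    stop("lambda grid is not a full rectangular grid")
  g <- array(NA_real_, c(n1, n2, 2L, 2L))
  sdet <- matrix(NA_real_, n1, n2)
  for (r in seq_len(nrow(grid))) {
    i <- match(grid[r, 1L], l1)
    j <- match(grid[r, 2L], l2)
    gij <- if (is_tensor_metric(met)) met$value[r, , ]
           else diag(rep(met$value[r], 2L))
    g[i, j, , ] <- gij
    sdet[i, j] <- sqrt(max(det(gij), 0))
  }
  structure(list(l1 = l1, l2 = l2, g = g, sqrt_det = sdet, estimate = met),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  cat(sprintf("metric_field: %d x %d grid, sqrt(det g) in [%.3g, %.3g]\n",
              length(x$l1), length(x$l2), min(x$sqrt_det), max(x$sqrt_det)))
  invisible(x)
}

# bilinear interpolation of the tensor field at lambda = c(u, v)
field_tensor_at <- function(field, lam) {
  u <- min(max(lam[1], field$l1[1]), tail(field$l1, 1))
  v <- min(max(lam[2], field$l2[1]), tail(field$l2, 1))
  i <- max(1L, min(findInterval(u, field$l1), length(field$l1) - 1L))
  j <- max(1L, min(findInterval(v, field$l2), length(field$l2) - 1L))
  tu <- (u - field$l1[i]) / (field$l1[i + 1] - field$l1[i])
  tv <- (v - field$l2[j]) / (field$l2[j + 1] - field$l2[j])
  (1 - tu) * (1 - tv) * field$g[i, j, , ] +
    tu * (1 - tv) * field$g[i + 1, j, , ] +
    (1 - tu) * tv * field$g[i, j + 1, , ] +
    tu * tv * field$g[i + 1, j + 1, , ]
}
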