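#' Lambda path
#'
#' An ordered sequence of lambda vectors connecting state A to state B,
#' parameterized by `s` in \[0, 1\] (strictly increasing, `s[1] = 0`,
#' `s[n] = 1`). By default `s` is the normalized cumulative Euclidean arc
#' length in lambda space.
#'
#' @param points numeric matrix (one row per point, one column per lambda
#'   component) or vector for a 1D path; each component must lie in
#'   \[0, 1\].
#' @param s optional parameter values.
#' @return an object of class `lambda_path`.
#' @export
lambda_path <- function(points, s = NULL) {
  pts <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 1L)
  n <- nrow(pts)
  if (n < 2L) stop("a path needs at least two points")
  if (any(pts < -1e-12) || any(pts > 1 + 1e-12))
    stop("lambda components must lie in [0, 1]")
  if (is.null(s)) {
    seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-n, , drop = FALSE])^2))
    if (all(seg == 0)) stop("degenerate path: all points identical")
    s <- c(0, cumsum(seg)) / sum(seg)
  }
  s <- as.numeric(s)
  if (length(s) != n || s[1L] != 0 || abs(s[n] - 1) > 1e-12 ||
      any(diff(s) <= 0))
    stop("s must be strictly increasing from 0 to 1")
  structure(list(points = pts, s = s, n_dims = ncol(pts)),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("lambda_path: %d points in %d dimension(s), (%s) -> (%s)\n",
              nrow(x$points), x$n_dims,
              paste(signif(x$points[1, ], 3), collapse = ", "),
              paste(signif(x$points[nrow(x$points), ], 3), collapse = ", ")))
  invisible(x)
}

#' Standard path constructions
#'
#' `build_simultaneous_path()` couples all lambda components together along
#' the diagonal with `n_points` equidistant points.
#' `build_sequential_path()` changes one component at a time (legs in
#' `component_order`), sharing the corner points, e.g. 21 points in two
#' dimensions gives the 11 + 11 - 1 structure.
#' `build_three_leg_path()` builds the channel path
#' `(0,0) -> (c,0) -> (c,1) -> (1,1)` in `(lambda_coulomb, lambda_other)`
#' with points distributed over the legs proportionally to leg length;
#' `channel_value = 0` degenerates to the sequential path.
#'
#' @param n_points total number of path points.
#' @param n_dims number of lambda components.
#' @param component_order order in which components are switched on.
#' @param channel_value the `lambda_coulomb` value of the middle leg.
#' @return a [lambda_path()].
#' @export
build_simultaneous_path <- function(n_points, n_dims = 1L) {
  stopifnot(n_points >= 2L)
  u <- seq(0, 1, length.out = n_points)
  lambda_path(matrix(rep(u, n_dims), ncol = n_dims))
}

#' @rdname build_simultaneous_path
#' @export
build_sequential_path <- function(n_points, n_dims = 2L,
                                  component_order = seq_len(n_dims)) {
  stopifnot(n_points >= n_dims + 1L,
            setequal(component_order, seq_len(n_dims)))
  if (n_dims == 1L) return(build_simultaneous_path(n_points, 1L))
  corners <- matrix(0, n_dims + 1L, n_dims)
  for (leg in seq_len(n_dims)) {
    corners[leg + 1L, ] <- corners[leg, ]
    corners[leg + 1L, component_order[leg]] <- 1
  }
  path_through_corners(corners, n_points)
}

#' @rdname build_simultaneous_path
#' @export
build_three_leg_path <- function(channel_value = 0.5, n_points = 21L) {
  stopifnot(channel_value >= 0, channel_value <= 1, n_points >= 4L)
  corners <- rbind(c(0, 0), c(channel_value, 0), c(channel_value, 1),
                   c(1, 1))
  path_through_corners(corners, n_points)
}

# distribute n_points over the polyline through `corners`, proportionally
# to leg length (largest-remainder rounding); zero-length legs are dropped
path_through_corners <- function(corners, n_points) {
  nleg <- nrow(corners) - 1L
  len <- sqrt(rowSums((corners[-1L, , drop = FALSE] -
                         corners[-nrow(corners), , drop = FALSE])^2))
  keep <- len > 0
  corners <- corners[c(TRUE, keep), , drop = FALSE]
  len <- len[keep]
  nleg <- length(len)
  nseg <- n_points - 1L
  raw <- nseg * len / sum(len)
  counts <- floor(raw)
  rem <- nseg - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  counts[counts == 0 & len > 0] <- pmax(counts[counts == 0 & len > 0], 1L)
  # re-balance if the minimum bump overflowed
  while (sum(counts) > nseg) {
    i <- which.max(counts)
    counts[i] <- counts[i] - 1L
  }
  pts <- corners[1L, , drop = FALSE]
  for (leg in seq_len(nleg)) {
    if (counts[leg] == 0) next
    tt <- seq_len(counts[leg]) / counts[leg]
    seg <- outer(1 - tt, corners[leg, ]) + outer(tt, corners[leg + 1L, ])
    pts <- rbind(pts, seg)
  }
  lambda_path(pts)
}

# resolve a metric specification along a path into per-point values:
# scalars (vector / scalar metric_estimate / function(lambda)->scalar) or
# tensors (tensor metric_estimate / metric_field / function -> matrix).
# Returns list(kind = "scalar"/"tensor", at = function(i) value for point i)
metric_along_path <- function(path, metric) {
  pts <- path$points
  n <- nrow(pts)
  if (is.numeric(metric) && !is.matrix(metric)) {
    stopifnot(length(metric) == n)
    vals <- metric
    return(list(kind = "scalar", values = vals))
  }
  if (inherits(metric, "metric_field")) {
    vals <- lapply(seq_len(n), function(i) field_tensor_at(metric, pts[i, ]))
    return(list(kind = "tensor", values = vals))
  }
  if (inherits(metric, "metric_estimate")) {
    if (is_tensor_metric(metric)) {
      stopifnot(nrow(metric$lambda) == n)
      vals <- lapply(seq_len(n), function(i) metric$value[i, , ])
      return(list(kind = "tensor", values = vals))
    }
    if (nrow(metric$lambda) == n) return(list(kind = "scalar",
                                              values = metric$value))
    # interpolate a 1D profile onto the path's own parameter
    stopifnot(path$n_dims == 1L)
    vals <- approx(metric$lambda[, 1L], metric$value, xout = pts[, 1L],
                   rule = 2)$y
    return(list(kind = "scalar", values = vals))
  }
  if (is.function(metric)) {
    vals <- lapply(seq_len(n), function(i) metric(pts[i, ]))
    if (length(vals[[1]]) == 1L)
      return(list(kind = "scalar", values = vapply(vals, as.numeric,
                                                   numeric(1))))
    return(list(kind = "tensor", values = vals))
  }
  stop("unsupported metric specification")
}

# per-segment metric lengths l_i = sqrt(dl' gbar dl), gbar = endpoint mean
segment_lengths <- function(path, metric) {
  m <- metric_along_path(path, metric)
  pts <- path$points
  n <- nrow(pts)
  dl <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  if (m$kind == "scalar") {
    if (any(m$values < 0)) stop("negative metric along the path")
    gbar <- (m$values[-1L] + m$values[-n]) / 2
    sqrt(pmax(rowSums(dl^2) * gbar, 0))
  } else {
    vapply(seq_len(n - 1L), function(i) {
      gbar <- (m$values[[i]] + m$values[[i + 1L]]) / 2
      q <- as.numeric(t(dl[i, ]) %*% gbar %*% dl[i, ])
      if (q < -1e-12) stop("negative metric along the path")
      sqrt(max(q, 0))
    }, numeric(1))
  }
}

#' Thermodynamic length of a path
#'
#' Discrete version of
#' \eqn{\mathcal{L} = \int_0^1 \sqrt{\dot\lambda^\mu g_{\mu\nu}
#'  \dot\lambda^\nu}\, ds}: the sum over segments of
#' `sqrt(dlambda' gbar dlambda)` with `gbar` the mean of the endpoint
#' metric values (or tensors). Additive under path concatenation.
#'
#' @param path a [lambda_path()].
#' @param metric per-point metric: a numeric vector, a [metric_estimate()],
#'   a `metric_field` (bilinear interpolation), or a function
#'   `lambda -> g`.
#' @return the path length (units sqrt(energy^2 x time)).
#' @export
path_length <- function(path, metric) {
  sum(segment_lengths(path, metric))
}

#' Variance functional of a sampling distribution along a path
#'
#' The efficiency measure \eqn{\mathbb{V} = \int_0^1 g(\lambda)/\pi_\lambda
#' d\lambda} in per-segment discrete form \eqn{\sum_i \ell_i^2/\pi_i} (with
#' \eqn{\ell_i} the segment metric lengths), together with the implied
#' variance `2 V / tau` of the free-energy estimate for total sampling time
#' `tau`. The discretization matches [path_length()], so the Cauchy-Schwarz
#' bound `V >= L^2` is exact, with equality at the optimal target.
#'
#' @inheritParams path_length
#' @param target sampling fractions: `NULL` for uniform, a per-segment
#'   vector (length `n - 1`), or a per-point vector (length `n`, averaged
#'   onto segments); must be positive, normalized internally.
#' @param total_time total sampling time `tau` (> 0) for the variance.
#' @return a list with `V`, `var` (`2 V / tau`, `NA` if no `total_time`),
#'   and the per-segment lengths `ell`.
#' @export
variance_functional <- function(path, metric, target = NULL,
                                total_time = NULL) {
  ell <- segment_lengths(path, metric)
  ns <- length(ell)
  pi_seg <- if (is.null(target)) rep(1 / ns, ns) else as.numeric(target)
  if (length(pi_seg) == ns + 1L)
    pi_seg <- (pi_seg[-1L] + pi_seg[-(ns + 1L)]) / 2
  if (length(pi_seg) != ns || any(pi_seg <= 0))
    stop("target must be positive, per segment or per point")
  pi_seg <- pi_seg / sum(pi_seg)
  V <- sum(ell^2 / pi_seg)
  list(V = V,
       var = if (is.null(total_time)) NA_real_ else 2 * V / total_time,
       ell = ell)
}

#' Optimal target distribution along a path
#'
#' The variance-minimizing sampling fractions `pi proportional to
#' sqrt(lambda-dot' g lambda-dot)` (per segment), for which the
#' Cauchy-Schwarz bound is saturated and `V = L^2`. Invariant under overall
#' scaling of the metric. Also returns the per-point density
#' `sqrt(g)/L` evaluated at the path nodes (1D form).
#'
#' @inheritParams path_length
#' @return a list with `segment` (normalized per-segment fractions),
#'   `point` (normalized per-point weights) and `density` (per-point
#'   continuous density `sqrt(g)/L`).
#' @export
optimal_target <- function(path, metric) {
  ell <- segment_lengths(path, metric)
  L <- sum(ell)
  if (L <= 0) {
    ns <- length(ell)
    return(list(segment = rep(1 / ns, ns),
                point = rep(1 / (ns + 1), ns + 1),
                density = rep(1, ns + 1)))
  }
  seg <- ell / L
  # node weights: half-segment shares
  n <- length(ell) + 1L
  pt <- numeric(n)
  pt[1L] <- seg[1L] / 2
  pt[n] <- seg[n - 1L] / 2
  if (n > 2L) pt[2:(n - 1L)] <- (seg[-1L] + seg[-(n - 1L)]) / 2
  m <- metric_along_path(path, metric)
  if (m$kind == "scalar") {
    dens <- sqrt(pmax(m$values, 0)) / L
  } else {
    # per-point metric speed along the (unit-tangent) path direction
    pts <- path$points
    dens <- vapply(seq_len(n), function(i) {
      i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
      tg <- pts[i1, ] - pts[i0, ]
      nt <- sqrt(sum(tg^2))
      if (nt == 0) return(0)
      tg <- tg / nt
      sqrt(max(as.numeric(t(tg) %*% m$values[[i]] %*% tg), 0)) / L
    }, numeric(1))
  }
  list(segment = seg, point = pt / sum(pt), density = dens)
}

#' Theoretical improvement factor of target optimization
#'
#' `IF = V_opt / V_unif = L^2 / V_unif`, always in (0, 1]; 1 exactly when
#' the metric is constant along the path. The factor is the predicted
#' reduction in computational time (after equilibration) from switching the
#' sampling distribution from uniform to optimal.
#'
#' @inheritParams path_length
#' @return the improvement factor.
#' @export
improvement_factor <- function(path, metric) {
  ell <- segment_lengths(path, metric)
  L <- sum(ell)
  Vu <- sum(ell^2) * length(ell)
  if (Vu == 0) return(1)
  L^2 / Vu
}

#' Reparameterize a path to constant metric speed
#'
#' Redistributes the path points so that every segment carries the same
#' metric length (inversion of the cumulative-length function by linear
#' interpolation along the polyline); the endpoints are kept fixed. With a
#' constant metric the spacing is unchanged.
#'
#' @inheritParams path_length
#' @param n_points number of points of the reparameterized path (default:
#'   same as input).
#' @return a [lambda_path()] with equal metric length per segment.
#' @export
reparameterize_path <- function(path, metric, n_points = NULL) {
  ell <- segment_lengths(path, metric)
  n <- nrow(path$points)
  n_out <- n_points %||% n
  cum <- c(0, cumsum(ell))
  if (cum[n] <= 0) stop("zero total metric length")
  cum <- cum / cum[n]
  targets <- seq(0, 1, length.out = n_out)
  new_pts <- matrix(NA_real_, n_out, path$n_dims)
  for (k in seq_len(n_out)) {
    u <- targets[k]
    i <- max(1L, min(findInterval(u, cum), n - 1L))
    t0 <- (u - cum[i]) / max(cum[i + 1L] - cum[i], .Machine$double.eps)
    new_pts[k, ] <- (1 - t0) * path$points[i, ] + t0 * path$points[i + 1L, ]
  }
  new_pts[1L, ] <- path$points[1L, ]
  new_pts[n_out, ] <- path$points[n, ]
  lambda_path(new_pts)
}

#' Shortest metric path on a 2D lambda grid
#'
#' Minimum-cost path between two nodes of the rectangular grid underlying a
#' `metric_field`, moving between 8-connected neighbors with edge cost
#' `sqrt(dlambda' gbar dlambda)` (`gbar` = mean of the endpoint tensors).
#' Optionally restricts the search to the band `|lambda_1 - lambda_2| <= d`
#' (plus the start/end nodes). Scaling the field by `c` scales the cost by
#' `sqrt(c)` and leaves the minimizing path unchanged.
#'
#' @param field a `metric_field` (see [metric_field_2d()]).
#' @param start,end lambda vectors of the end states (matched to the
#'   nearest grid nodes); defaults to `(0,0)` and `(1,1)`.
#' @param band optional band half-width `d`, or `NULL` for no constraint.
#' @return a list with `path` (a [lambda_path()]), `cost` (its discrete
#'   metric length) and `indices` (grid indices of the nodes).
#' @export
optimize_path_2d <- function(field, start = c(0, 0), end = c(1, 1),
                             band = NULL) {
  stopifnot(inherits(field, "metric_field"))
  n1 <- length(field$l1); n2 <- length(field$l2)
  id <- function(i, j) (j - 1L) * n1 + i
  istart <- c(which.min(abs(field$l1 - start[1])),
              which.min(abs(field$l2 - start[2])))
  iend <- c(which.min(abs(field$l1 - end[1])),
            which.min(abs(field$l2 - end[2])))
  feas <- matrix(TRUE, n1, n2)
  if (!is.null(band)) {
    for (i in seq_len(n1)) for (j in seq_len(n2))
      feas[i, j] <- abs(field$l1[i] - field$l2[j]) <= band + 1e-12
    feas[istart[1], istart[2]] <- TRUE
    feas[iend[1], iend[2]] <- TRUE
  }
  moves <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (!feas[i, j]) next
    for (m in seq_len(nrow(moves))) {
      i2 <- i + moves[m, 1]; j2 <- j + moves[m, 2]
      if (i2 < 1 || i2 > n1 || j2 < 1 || j2 > n2 || !feas[i2, j2]) next
      dl <- c(field$l1[i2] - field$l1[i], field$l2[j2] - field$l2[j])
      gbar <- (field$g[i, j, , ] + field$g[i2, j2, , ]) / 2
      q <- as.numeric(t(dl) %*% gbar %*% dl)
      from <- c(from, id(i, j)); to <- c(to, id(i2, j2))
      wt <- c(wt, sqrt(max(q, 0)))
    }
  }
  gr <- igraph::make_graph(rbind(from, to), n = n1 * n2, directed = FALSE)
  sp <- suppressWarnings(
    igraph::shortest_paths(gr, from = id(istart[1], istart[2]),
                           to = id(iend[1], iend[2]), weights = wt,
                           output = "both"))
  vpath <- as.integer(sp$vpath[[1]])
  if (length(vpath) == 0)
    stop(sprintf("no feasible path within band |l1 - l2| <= %s", band))
  cost <- sum(wt[as.integer(sp$epath[[1]])])
  idx <- cbind(((vpath - 1L) %% n1) + 1L, ((vpath - 1L) %/% n1) + 1L)
  pts <- cbind(field$l1[idx[, 1]], field$l2[idx[, 2]])
  list(path = lambda_path(pts), cost = cost, indices = idx)
}
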