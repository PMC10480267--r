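# Shared helpers and independent oracles used across the test suite.

# central finite difference of a scalar function of one lambda component
fd_dlambda <- function(f, lam, k = 1L, h = 1e-5) {
  lp <- lam; lm <- lam
  lp[k] <- lam[k] + h
  lm[k] <- lam[k] - h
  (f(lp) - f(lm)) / (2 * h)
}

# plain LJ + Coulomb potential of one end state (independent re-derivation)
plain_state_potential <- function(r, eps, sigma, q) {
  4 * eps * ((sigma / r)^12 - (sigma / r)^6) + q / r
}

# exact OU (AR(1)) series of x^2-type generalized force for the harmonic toy
ou_series <- function(n, k, gamma = 1, beta = 1, dt = 0.05) {
  a <- exp(-k * dt / gamma)
  sdst <- sqrt(1 / (beta * k))
  x <- as.numeric(stats::filter(rnorm(n, sd = sdst * sqrt(1 - a^2)), a,
                                "recursive", init = rnorm(1, sd = sdst)))
  x
}

# build a metric_field directly from an array of 2x2 tensors
make_field <- function(g) {
  n1 <- dim(g)[1]; n2 <- dim(g)[2]
  grid <- as.matrix(expand.grid(seq(0, 1, length.out = n1),
                                seq(0, 1, length.out = n2)))
  np <- nrow(grid)
  val <- array(NA_real_, c(np, 2, 2))
  for (r in seq_len(np)) {
    i <- round(grid[r, 1] * (n1 - 1)) + 1
    j <- round(grid[r, 2] * (n2 - 1)) + 1
    val[r, , ] <- g[i, j, , ]
  }
  metric_field_from_estimate(
    metric_estimate(grid, val, estimator = "friction"))
}

# exhaustive branch-and-bound shortest path over ALL simple 8-connected
# grid paths; independent of the igraph-based implementation
bf_shortest_path <- function(field, si = 1, sj = 1, ei = NULL, ej = NULL) {
  n1 <- length(field$l1); n2 <- length(field$l2)
  ei <- ei %||% n1; ej <- ej %||% n2
  moves <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  ecost <- function(i, j, i2, j2) {
    dl <- c(field$l1[i2] - field$l1[i], field$l2[j2] - field$l2[j])
    gbar <- (field$g[i, j, , ] + field$g[i2, j2, , ]) / 2
    sqrt(max(as.numeric(t(dl) %*% gbar %*% dl), 0))
  }
  best <- Inf
  visited <- matrix(FALSE, n1, n2)
  dfs <- function(i, j, cost) {
    if (cost >= best) return()
    if (i == ei && j == ej) { best <<- cost; return() }
    visited[i, j] <<- TRUE
    for (m in 1:8) {
      i2 <- i + moves[m, 1]; j2 <- j + moves[m, 2]
      if (i2 < 1 || i2 > n1 || j2 < 1 || j2 > n2 || visited[i2, j2]) next
      dfs(i2, j2, cost + ecost(i, j, i2, j2))
    }
    visited[i, j] <<- FALSE
  }
  dfs(si, sj, 0)
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard settings for exact-OU harmonic sampling in tests
ou_settings <- function(seed, n_steps = 50000L, sample_interval = 10L,
                        dt = 0.05) {
  sampler_settings(timestep = dt, n_steps = n_steps,
                   sample_interval = sample_interval, seed = seed,
                   move_kind = "exact_ou")
}
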