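test_that("integrated correlation matches closed-form oracles", {
  # constant series: zero
  expect_error(integrated_correlation(rep(1, 10), dt = 1), "too short")
  expect_equal(as.numeric(integrated_correlation(rep(2, 100), dt = 0.5)), 0)
  # i.i.d. noise with variance v: only C0/2 survives, value v * dt / 2
  set.seed(1)
  v <- 2.5; dt <- 0.2
  vals <- vapply(1:20, function(i)
    as.numeric(integrated_correlation(rnorm(4000, sd = sqrt(v)), dt = dt)),
    numeric(1))
  se <- sd(vals) / sqrt(20)
  expect_lt(abs(mean(vals) - v * dt / 2), 3 * se)
  # exponentially correlated series: integral v * tau_c
  set.seed(2)
  tau_c <- 2; dt2 <- 0.1
  a <- exp(-dt2 / tau_c)
  x <- as.numeric(filter(rnorm(200000, sd = sqrt(1 - a^2)), a, "recursive"))
  est <- as.numeric(integrated_correlation(x, dt = dt2))
  expect_equal(est, var(x) * tau_c, tolerance = 0.1)
})

test_that("friction metric reproduces the overdamped harmonic closed form", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  run <- run_fixed_lambda(sys, lambda_grid(5),
                          ou_settings(3, n_steps = 200000L,
                                      sample_interval = 4L), th)
  fm <- friction_metric(run)
  exact <- alchpath:::harmonic_friction_exact(sys, run$lambda_grid[, 1])
  expect_equal(fm$value, exact, tolerance = 0.15)
  expect_true(all(fm$value >= 0))
  expect_true(all(fm$se > 0))
  # zero-fluctuation series gives zero
  zs <- force_series(matrix(1.3, 200, 1), dt = 0.1, lambda = 0.5)
  expect_equal(friction_metric(list(zs))$value, 0)
})

test_that("friction metric scales linearly with the friction coefficient", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  # exact OU at gamma and 2 gamma: g doubles
  g1 <- friction_metric(run_fixed_lambda(
    sys, 0.5, sampler_settings(timestep = 0.05, n_steps = 150000L,
                               sample_interval = 4L, seed = 5,
                               friction_gamma = 1,
                               move_kind = "exact_ou"), th))$value
  g2 <- friction_metric(run_fixed_lambda(
    sys, 0.5, sampler_settings(timestep = 0.1, n_steps = 150000L,
                               sample_interval = 4L, seed = 6,
                               friction_gamma = 2,
                               move_kind = "exact_ou"), th))$value
  expect_equal(g2 / g1, 2, tolerance = 0.25)
})

test_that("window rule is stable under halving and doubling of the cap", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  run <- run_fixed_lambda(sys, 0.2, ou_settings(9, n_steps = 200000L,
                                                sample_interval = 4L), th)
  w_auto <- attr(integrated_correlation(run$series[[1]]$values[, 1],
                                        dt = run$series[[1]]$dt), "window")
  g_half <- friction_metric(run, window = ceiling(w_auto / 2))$value
  g_auto <- friction_metric(run)$value
  g_double <- friction_metric(run, window = 2L * w_auto)$value
  expect_equal(g_half / g_auto, 1, tolerance = 0.15)
  expect_equal(g_double / g_auto, 1, tolerance = 0.15)
})

test_that("Fisher-Rao metric equals the equal-time force variance", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  run <- run_fixed_lambda(sys, lambda_grid(3),
                          ou_settings(7, n_steps = 100000L,
                                      sample_interval = 2L), th)
  fr <- fisher_rao_metric(run)
  exact <- alchpath:::harmonic_fisher_rao_exact(sys, run$lambda_grid[, 1])
  expect_equal(fr$value, exact, tolerance = 0.1)
  # scaling the forces by c scales the metric by c^2
  scaled <- run
  for (i in seq_along(scaled$series))
    scaled$series[[i]]$values <- 3 * scaled$series[[i]]$values
  expect_equal(fisher_rao_metric(scaled)$value, 9 * fr$value)
  # constant series: zero
  zs <- force_series(matrix(0.7, 100, 1), dt = 1, lambda = 0)
  expect_equal(fisher_rao_metric(list(zs))$value, 0)
})

test_that("diffusion metric reduces to the friction metric on a one-point grid", {
  set.seed(12)
  x <- ou_series(5000, k = 2)
  f <- 1.5 * x^2
  dts <- 0.05
  traj <- structure(list(w = matrix(1, 5000, 1),
                         dhdl_grid = matrix(f, 5000, 1),
                         ilam = rep(1L, 5000),
                         lambda_grid = matrix(0.5, 1, 1),
                         n_lambda_dims = 1L, beta = 1, dt = dts),
                    class = "ee_trajectory")
  dm <- diffusion_metric(traj)
  fm <- friction_metric(list(force_series(f, dt = dts, lambda = 0.5)))
  expect_equal(dm$value, fm$value, tolerance = 1e-12)
  # zero fluctuations: zero everywhere
  traj0 <- traj
  traj0$dhdl_grid <- matrix(2, 5000, 1)
  expect_equal(diffusion_metric(traj0)$value, 0)
})

test_that("diffusion and friction metrics agree in shape on the harmonic toy", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  run <- run_fixed_lambda(sys, lambda_grid(9),
                          ou_settings(15, n_steps = 150000L,
                                      sample_interval = 4L), th)
  fm <- friction_metric(run)
  bias <- awh_bias(lambda_grid(9), initial_error = 10,
                   update_interval = 100L)
  set <- sampler_settings(timestep = 0.05, seed = 16,
                          move_kind = "exact_ou",
                          lambda_move_interval = 4L, sample_interval = 1L)
  ee <- run_expanded_ensemble(sys, bias, set, th, n_updates = 400L,
                              record = TRUE)
  dm <- diffusion_metric(ee$trajectory)
  # both profiles decay over more than a decade and track each other
  expect_gt(max(fm$value) / min(fm$value), 10)
  expect_gt(cor(log(dm$value), log(fm$value)), 0.95)
  # same order of magnitude throughout
  expect_true(all(dm$value / fm$value > 1 / 4 & dm$value / fm$value < 4))
})

test_that("never-visited points are reported missing and interpolable", {
  set.seed(4)
  n <- 400
  w <- cbind(runif(n, 0.4, 0.6), 0, runif(n, 0.4, 0.6))
  w <- w / rowSums(w)
  f <- matrix(rnorm(3 * n), n, 3) + 2
  traj <- structure(list(w = w, dhdl_grid = f, ilam = rep(1L, n),
                         lambda_grid = matrix(c(0, 0.5, 1), 3, 1),
                         n_lambda_dims = 1L, beta = 1, dt = 0.1),
                    class = "ee_trajectory")
  dm <- diffusion_metric(traj)
  expect_true(is.na(dm$value[2]))
  dmi <- diffusion_metric(traj, interpolate = TRUE)
  expect_false(is.na(dmi$value[2]))
  expect_true(dmi$interpolated[2])
})

test_that("2D metric fields are symmetric and reduce to the 1D estimator", {
  th <- thermo_params()
  sys <- two_lambda_system()
  l <- seq(0, 1, 0.5)
  grid <- as.matrix(expand.grid(l, l))
  set <- sampler_settings(timestep = 0.002, n_steps = 30000L,
                          sample_interval = 10L, seed = 19)
  run <- run_fixed_lambda(sys, grid, set, th)
  fm <- friction_metric(run)
  fld <- metric_field_from_estimate(fm)
  for (r in seq_len(nrow(grid))) {
    g <- fm$value[r, , ]
    expect_equal(g, t(g))
    expect_true(all(eigen(g, symmetric = TRUE)$values >= 0))
  }
  expect_equal(dim(fld$g), c(3L, 3L, 2L, 2L))
  expect_equal(fld$sqrt_det[1, 1],
               sqrt(max(det(fm$value[1, , ]), 0)))
  # a diagonal-component series run through the 1D estimator agrees with
  # the corresponding tensor component
  fs <- run$series[[5]]
  one <- force_series(fs$values[, 2, drop = FALSE], dt = fs$dt,
                      lambda = fs$lambda[2])
  g1d <- friction_metric(list(one))$value
  expect_equal(g1d, fm$value[5, 2, 2], tolerance = 1e-8)
})

test_that("independent isotropic force components give near-diagonal tensors", {
  set.seed(23)
  n <- 6000
  vals <- cbind(ou_series(n, k = 1.5), ou_series(n, k = 1.5))
  fs <- force_series(vals, dt = 0.05, lambda = c(0.5, 0.5))
  fm <- friction_metric(list(fs))
  g <- fm$value[1, , ]
  expect_lt(abs(g[1, 2]), 0.35 * sqrt(g[1, 1] * g[2, 2]))
})
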