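test_that("trapezoidal thermodynamic integration is exact for its oracles", {
  lam <- seq(0, 1, length.out = 21)
  expect_equal(ti_trapezoid(rep(2.5, 21), lam)$dG, 2.5)  # constant gradient
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  means <- harmonic_mean_gradient(sys, lam, th)
  expect_lt(abs(ti_trapezoid(means, lam)$dG - log(4) / 2), 1e-3)
  # reversed grid negates the free energy difference
  expect_equal(ti_trapezoid(rev(means), rev(lam))$dG,
               -ti_trapezoid(means, lam)$dG)
  # standard errors propagate in quadrature with the trapezoid weights
  r <- ti_trapezoid(means, lam, se = rep(0.1, 21))
  dl <- diff(lam)
  w <- c(dl / 2, 0) + c(0, dl / 2)
  expect_equal(r$se, sqrt(sum((w * 0.1)^2)))
})

test_that("TI converges at second order in the grid spacing", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  err <- vapply(c(6, 11, 21, 41), function(n) {
    lam <- seq(0, 1, length.out = n)
    abs(ti_trapezoid(harmonic_mean_gradient(sys, lam, th), lam)$dG -
          log(4) / 2)
  }, numeric(1))
  # halving the spacing reduces the error by about 4
  expect_equal(err[1] / err[2], 4, tolerance = 0.4)
  expect_equal(err[2] / err[3], 4, tolerance = 0.4)
  expect_equal(err[3] / err[4], 4, tolerance = 0.4)
})

test_that("BAR solves the Bennett self-consistency equation", {
  # mirror-symmetric forward and reverse work: dG = 0
  set.seed(1)
  w <- rnorm(500, 0.7, 1.3)
  expect_equal(bar_pair(w, w)$dG, 0, tolerance = 1e-10)
  # Crooks-consistent Gaussian work: forward N(dG + s^2/2, s^2),
  # reverse N(-dG + s^2/2, s^2) with dG = 1, sigma = 1
  set.seed(2)
  r <- bar_pair(rnorm(5000, 1.5, 1), rnorm(5000, -0.5, 1))
  expect_lt(abs(r$dG - 1), 3 * r$se)
  expect_true(r$breakdown$overlap_ok)
  expect_error(bar_pair(numeric(0), rnorm(10)), "nonempty")
})

test_that("BAR is exact for enumerable four-microstate systems", {
  # two 4-microstate systems with exactly representable Boltzmann weights
  pA <- c(1, 2, 3, 4) / 10
  pB <- c(4, 1, 1, 4) / 10
  EA <- -log(pA)           # Z_A = 1
  EB <- -log(pB) + 0.7     # Z_B = exp(-0.7)
  dG_exact <- 0.7          # -log(Z_B / Z_A)
  # exhaustive Boltzmann-weighted samples: microstate i drawn n * p_i times
  n <- 100
  idxA <- rep(1:4, times = n * pA)
  idxB <- rep(1:4, times = n * pB)
  wf <- EB[idxA] - EA[idxA]
  wr <- EA[idxB] - EB[idxB]
  expect_equal(bar_pair(wf, wr)$dG, dG_exact, tolerance = 1e-8)
})

test_that("BAR bias shrinks with sample size", {
  est_bias <- function(n, nrep) {
    mean(vapply(seq_len(nrep), function(i)
      bar_pair(rnorm(n, 1.5, 1), rnorm(n, -0.5, 1))$dG - 1, numeric(1)))
  }
  set.seed(33)
  b_small <- est_bias(100, 150)
  b_large <- est_bias(10000, 60)
  expect_lt(abs(b_large), abs(b_small))
  expect_lt(abs(b_large), 3 * 1 / sqrt(60 * 10000))  # within noise of zero
})

test_that("BAR chains sum legs and are order invariant", {
  th <- thermo_params()
  # all-zero legs
  eds <- structure(list(forward = list(rep(0, 50), rep(0, 50)),
                        reverse = list(rep(0, 50), rep(0, 50)),
                        N_k = c(50L, 50L, 50L)),
                   class = "energy_diff_set")
  expect_equal(bar_chain(eds, th)$dG, 0)
  # harmonic ladder against the analytic value
  sys <- harmonic_system(1, 4)
  run <- run_fixed_lambda(sys, lambda_grid(9),
                          ou_settings(51, n_steps = 80000L), th)
  bc <- bar_chain(run, th)
  expect_lt(abs(bc$dG - log(4) / 2), 4 * bc$se + 0.02)
  # permuting the leg order leaves the total unchanged
  eds2 <- energy_differences(run)
  perm <- sample(length(eds2$forward))
  eds3 <- structure(list(forward = eds2$forward[perm],
                         reverse = eds2$reverse[perm], N_k = eds2$N_k),
                    class = "energy_diff_set")
  expect_equal(bar_chain(eds3, th)$dG, bc$dG)
})

test_that("MBAR reduces to BAR for two states and solves the ladder", {
  set.seed(61)
  # K = 2 equivalence to 1e-8
  wf <- rnorm(800, 1.5, 1)
  wr <- rnorm(600, -0.5, 1)
  u_kn <- rbind(c(rep(0, 800), wr), c(wf, rep(0, 600)))
  m <- mbar_solve(u_kn, c(800L, 600L))
  expect_equal(m$result$dG, bar_pair(wf, wr)$dG, tolerance = 1e-8)
  # all states identical: all f zero
  u0 <- matrix(rep(rnorm(300), each = 3), 3, 300)
  expect_equal(mbar_solve(u0, c(100L, 100L, 100L))$f, rep(0, 3))
  # harmonic ladder k in {1, 2, 4}: f_k = log(k)/2 within 3 SE
  th <- thermo_params()
  set.seed(62)
  n <- 20000
  xs <- lapply(c(1, 2, 4), function(k) rnorm(n, sd = sqrt(1 / k)))
  u_kn <- do.call(cbind, lapply(xs, function(x)
    rbind(0.5 * 1 * x^2, 0.5 * 2 * x^2, 0.5 * 4 * x^2)))
  m2 <- mbar_solve(u_kn, rep(n, 3))
  expect_lt(abs(m2$f[2] - log(2) / 2), 3 * sqrt(m2$Theta[2, 2] +
                                                  m2$Theta[1, 1]))
  expect_lt(abs(m2$f[3] - log(4) / 2), 3 * m2$se_dG)
})

test_that("MBAR is at least as statistically efficient as the BAR chain", {
  # shared harmonic-ladder data, independent Gaussian samples per state:
  # using energy differences between all pairs (MBAR) must not lose
  # accuracy relative to adjacent pairs only (BAR chain)
  ks <- c(1, 1.7, 2.4, 3.2, 4)
  mkrun <- function(n, seed) {
    set.seed(seed)
    xs <- lapply(ks, function(k) rnorm(n, sd = sqrt(1 / k)))
    u <- lapply(xs, function(x) sapply(ks, function(k) 0.5 * k * x^2))
    structure(list(u = u, lambda_grid = matrix(seq(0, 1, length.out = 5)),
                   beta = 1),
              class = "fixed_lambda_run")
  }
  dg_mbar <- dg_bar <- numeric(100)
  for (s in 1:100) {
    run <- mkrun(200, 700 + s)
    dg_bar[s] <- bar_chain(energy_differences(run))$dG
    inp <- mbar_input(run)
    dg_mbar[s] <- mbar_solve(inp$u_kn, inp$N_k)$result$dG
  }
  expect_lt(sd(dg_mbar), sd(dg_bar))
  # both unbiased around the exact log(4)/2
  expect_lt(abs(mean(dg_mbar) - log(4) / 2), 3 * sd(dg_mbar) / 10)
  # the reported asymptotic MBAR error matches the empirical spread
  run1 <- mkrun(200, 1)
  inp1 <- mbar_input(run1)
  se1 <- mbar_solve(inp1$u_kn, inp1$N_k)$se_dG
  expect_equal(se1, sd(dg_mbar), tolerance = 0.35)
})

test_that("RMSE, bootstrap and empirical improvement factors behave as documented", {
  expect_equal(rmse_over_repeats(c(2, 2, 2), 2), 0)
  expect_equal(rmse_over_repeats(c(1, 3), 2), 1)
  set.seed(3)
  v <- rnorm(40)
  expect_equal(rmse_over_repeats(sample(v), 0.3),
               rmse_over_repeats(v, 0.3))
  # constant values: zero-width bootstrap interval
  bs <- bootstrap_sigma(rep(5, 30), seed = 1)
  expect_equal(bs$lower, bs$upper)
  # bootstrap SE of the mean of N(0,1), n = 100: about 0.1
  set.seed(8)
  x <- rnorm(100)
  bs2 <- bootstrap_sigma(x, statistic = mean, n_boot = 3000L, seed = 2)
  expect_equal(bs2$se, 0.1, tolerance = 0.2)
  # seeded determinism
  bs3 <- bootstrap_sigma(x, statistic = mean, n_boot = 500L, seed = 7)
  bs4 <- bootstrap_sigma(x, statistic = mean, n_boot = 500L, seed = 7)
  expect_identical(bs3, bs4)
  # empirical improvement factor is the squared RMSE ratio
  expect_equal(empirical_improvement_factor(1, 1), 1)
  expect_equal(round(empirical_improvement_factor(1.01, 1.52), 2), 0.44)
  expect_equal(round(empirical_improvement_factor(1.2, 4.9), 2), 0.06)
})

test_that("the repeat-evaluation report pools the mean as reference", {
  set.seed(12)
  ests <- rnorm(25, mean = 3, sd = 0.2)
  rep1 <- eval_report(ests, n_boot = 500L, seed = 4)
  expect_equal(rep1$reference, mean(ests))
  expect_equal(rep1$rmse, rmse_over_repeats(ests))
  expect_lte(rep1$ci$lower, rep1$rmse)
  expect_gte(rep1$ci$upper, rep1$rmse)
})

test_that("the predicted variance tracks the empirical variance on the micro-solvation toy", {
  th <- thermo_params()
  sys <- micro_solvation_system(n_solvent = 12, box = 5)
  grid <- seq(0, 1, length.out = 7)
  mk_set <- function(seed)
    sampler_settings(timestep = 1, seed = seed, move_kind = "metropolis",
                     mc_step = 0.3, lambda_move_interval = 26L,
                     sample_interval = 1L)
  b0 <- awh_bias(grid, initial_error = 10, update_interval = 100L)
  ee <- run_expanded_ensemble(sys, b0, mk_set(50), th, n_updates = 150L,
                              record = TRUE)
  V <- variance_functional(lambda_path(grid),
                           diffusion_metric(ee$trajectory))$V
  n_up <- 100L
  dgs <- vapply(1:40, function(s) {
    b <- awh_bias(grid, initial_error = 10, update_interval = 100L)
    r <- run_expanded_ensemble(sys, b, mk_set(100 + s), th,
                               n_updates = n_up, record = FALSE)
    awh_free_energy(r$bias, estimator = "tail_mean")$dG
  }, numeric(1))
  tau <- n_up * 100 * 26 * 1   # updates x moves/update x steps/move x dt
  ratio <- (2 * V / tau) / var(dgs)
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})
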