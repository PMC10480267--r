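test_that("bias initialization validates and normalizes the target", {
  b <- awh_bias(lambda_grid(21))
  expect_equal(b$target, rep(1 / 21, 21))
  expect_equal(b$f, rep(0, 21))
  expect_equal(b$stage, "initial")
  expect_equal(b$delta, 10 / 21)  # beta * initial_error / n_points
  expect_warning(b2 <- awh_bias(lambda_grid(4), target = c(1, 2, 3, 4)),
                 "renormalized")
  expect_equal(sum(b2$target), 1)
  expect_equal(b2$target, (1:4) / 10)
  expect_error(awh_bias(lambda_grid(3), initial_error = 0), "positive")
  expect_error(awh_bias(lambda_grid(3), target = c(1, -1, 1)), "positive")
})

test_that("sample accumulation is additive and conserving", {
  b <- awh_bias(lambda_grid(3))
  b <- awh_accumulate(b, c(1, 0, 0))
  expect_equal(b$hist, c(1, 0, 0))
  b <- awh_accumulate(b, c(0.2, 0.5, 0.3))
  expect_equal(sum(b$hist), 2)         # one unit per sample
  expect_equal(b$n_since_update, 2)
  # interleaved accumulation from two walkers equals their sum
  b1 <- awh_bias(lambda_grid(3))
  wA <- c(0.6, 0.3, 0.1); wB <- c(0.1, 0.1, 0.8)
  b1 <- awh_accumulate(awh_accumulate(b1, wA), wB)
  b2 <- awh_bias(lambda_grid(3))
  b2 <- awh_accumulate(b2, wA + wB, n = 2)
  expect_equal(b1$hist, b2$hist)
  expect_equal(b1$n_total, b2$n_total)
})

test_that("the bias update has the documented fixed point and gauge", {
  b <- awh_bias(lambda_grid(5), update_interval = 10L)
  # histogram exactly proportional to the target: f unchanged
  b <- awh_accumulate(b, b$target * 10, n = 10)
  b <- awh_update(b)
  expect_equal(b$f, rep(0, 5))
  # histogram reset, gauge fixed
  expect_equal(b$hist, rep(0, 5))
  expect_equal(b$f[1], 0)
  # update with no accumulated samples warns and is a no-op
  expect_warning(b2 <- awh_update(b), "no accumulated")
  expect_equal(b2$f, b$f)
  # the under-sampled point is raised relative to the over-sampled one
  b3 <- awh_bias(lambda_grid(2), update_interval = 10L)
  b3 <- awh_accumulate(b3, c(8, 2), n = 10)
  d3 <- b3$delta
  b3 <- awh_update(b3)
  expect_equal(b3$f, c(0, 1.2 * d3))
})

test_that("covering halves the update size and the stage exit is monotone", {
  b <- awh_bias(lambda_grid(4), initial_error = 100,
                update_interval = 10L, covering_threshold = 0.2)
  d0 <- b$delta
  # never-visited point: no covering
  b <- awh_accumulate(b, c(5, 5, 5, 0), n = 15)
  b <- awh_check_initial_stage(b)
  expect_equal(b$n_halvings, 0L)
  expect_equal(b$delta, d0)
  # scripted visits covering all points twice: two halvings
  b <- awh_accumulate(b, c(5, 5, 5, 5), n = 20)
  b <- awh_check_initial_stage(b)
  expect_equal(b$n_halvings, 1L)
  b <- awh_accumulate(b, c(3, 3, 3, 3), n = 12)
  b <- awh_check_initial_stage(b)
  expect_equal(b$n_halvings, 2L)
  expect_equal(b$delta, d0 / 4)
  # once final, the stage flag never returns to initial
  b$stage <- "final"; b$n_eff <- 100
  b <- awh_check_initial_stage(b)
  expect_equal(b$stage, "final")
})

test_that("a lambda-independent two-point system converges to f difference zero", {
  th <- thermo_params()
  sys <- harmonic_system(3, 3)
  dgs <- vapply(1:8, function(s) {
    b <- awh_bias(lambda_grid(2), initial_error = 5, update_interval = 50L)
    set <- sampler_settings(timestep = 0.05, seed = s,
                            move_kind = "exact_ou",
                            lambda_move_interval = 2L, sample_interval = 1L)
    ee <- run_expanded_ensemble(sys, b, set, th, n_updates = 200L,
                                record = FALSE)
    awh_free_energy(ee$bias)$dG
  }, numeric(1))
  expect_lt(abs(mean(dgs)), 3 * sd(dgs) / sqrt(8) + 0.02)
})

test_that("final-stage error decays like one over the square root of time", {
  th <- thermo_params()
  sys <- harmonic_system(1, 4)
  exact <- log(4) / 2
  traces <- vapply(1:20, function(s) {
    b <- awh_bias(lambda_grid(9), initial_error = 10, update_interval = 50L)
    set <- sampler_settings(timestep = 0.05, seed = s,
                            move_kind = "exact_ou",
                            lambda_move_interval = 5L, sample_interval = 1L)
    ee <- run_expanded_ensemble(sys, b, set, th, n_updates = 640L,
                                record = FALSE)
    ee$bias$dg_trace
  }, numeric(640))
  checkpoints <- c(40, 80, 160, 320, 640)
  rmse <- vapply(checkpoints, function(u)
    sqrt(mean((traces[u, ] - exact)^2)), numeric(1))
  slope <- coef(lm(log(rmse) ~ log(checkpoints)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("dynamic target updates follow sqrt(det g) with floor and cadence", {
  b <- awh_bias(lambda_grid(5), target_floor = 0.05,
                min_target_interval = 5L)
  met_const <- metric_estimate(lambda_grid(5), rep(2, 5),
                               estimator = "diffusion")
  # no-op in the initial stage
  b1 <- awh_dynamic_target(b, met_const)
  expect_equal(b1$target, rep(0.2, 5))
  b$stage <- "final"
  # constant metric: uniform target
  b2 <- awh_dynamic_target(b, met_const)
  expect_equal(b2$target, rep(0.2, 5))
  # g = (1 + lambda)^2 on a dense grid: pi(lambda) ~ (1 + lambda)/1.5
  lam <- seq(0, 1, length.out = 201)
  bd <- awh_bias(lam, target_floor = 0)
  bd$stage <- "final"
  met <- metric_estimate(lam, (1 + lam)^2, estimator = "diffusion")
  bd <- awh_dynamic_target(bd, met)
  dens <- bd$target / (lam[2] - lam[1])   # point weights -> density
  expect_equal(dens[2:200], ((1 + lam) / 1.5)[2:200], tolerance = 1e-2)
  # a second call within min_target_interval is a no-op
  bd$n_updates <- bd$n_updates + 2L
  met2 <- metric_estimate(lam, (2 - lam)^2, estimator = "diffusion")
  bd2 <- awh_dynamic_target(bd, met2)
  expect_equal(bd2$target, bd$target)
  # all-zero metric: uniform with a warning
  bz <- awh_bias(lambda_grid(4))
  bz$stage <- "final"
  metz <- metric_estimate(lambda_grid(4), rep(0, 4),
                          estimator = "diffusion")
  expect_warning(bz <- awh_dynamic_target(bz, metz), "uniform")
  expect_equal(bz$target, rep(0.25, 4))
  # floor: minimum target fraction is floor * max sqrt(g) before normalizing
  bf <- awh_bias(lambda_grid(3), target_floor = 0.5)
  bf$stage <- "final"
  metf <- metric_estimate(lambda_grid(3), c(100, 1e-8, 1e-8),
                          estimator = "diffusion")
  bf <- awh_dynamic_target(bf, metf)
  expect_equal(bf$target, c(10, 5, 5) / 20)
})

test_that("free energy readout respects the gauge and reports zero for flat f", {
  b <- awh_bias(lambda_grid(5))
  expect_equal(awh_free_energy(b)$dG, 0)
  b$f <- c(0, 0.1, 0.3, 0.5, 0.8)
  expect_equal(awh_free_energy(b)$dG, 0.8)
  b$f <- b$f + 7  # gauge shift leaves the difference unchanged
  expect_equal(awh_free_energy(b)$dG, 0.8)
})

test_that("bias state round-trips through JSON", {
  b <- awh_bias(lambda_grid(7), initial_error = 3, update_interval = 25L)
  b <- awh_accumulate(b, runif(7))
  b <- awh_update(b)
  f <- tempfile(fileext = ".json")
  awh_save(b, f)
  b2 <- awh_load(f)
  expect_equal(b2$f, b$f)
  expect_equal(b2$target, b$target)
  expect_equal(b2$grid, b$grid)
  expect_equal(b2$stage, b$stage)
  expect_equal(b2$delta, b$delta)
  unlink(f)
})

test_that("target distribution stays normalized through all operations", {
  set.seed(21)
  b <- awh_bias(lambda_grid(6), target = runif(6) + 0.5) |>
    suppressWarnings()
  for (i in 1:10) {
    w <- runif(6); w <- w / sum(w)
    b <- awh_accumulate(b, w)
    if (i %% 3 == 0) b <- awh_update(b)
    expect_equal(sum(b$target), 1)
  }
})
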