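#' Generate seeded test fixtures
#'
#' Writes a deterministic fixture set sufficient to exercise the metric and
#' estimator pipelines without running any simulation:
#' \itemize{
#'   \item `harmonic_dhdl_XX.xvg`: generalized-force time series of the
#'     harmonic toy at 21 equally spaced lambda points, sampled as exact
#'     AR(1) (Ornstein-Uhlenbeck) draws of `x` transformed to
#'     `(k_B - k_A) x^2 / 2`;
#'   \item `channel_field.csv`: a synthetic 2D metric tensor field with a
#'     low-metric channel at `lambda_1 = 0.5`;
#'   \item `crooks_work.csv`: forward/reverse Gaussian work samples
#'     consistent with the fluctuation theorem (`dG = 1`, `sigma = 1`);
#'   \item `example.xvg`: a small XVG file with legend metadata.
#' }
#'
#' @param outdir output directory (created if missing).
#' @param seed RNG seed; fixed seeds give identical files.
#' @param n_samples samples per harmonic force series.
#' @return invisibly, the vector of written file paths.
#' @export
generate_fixtures <- function(outdir, seed = 1L, n_samples = 400L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  with_seed(seed, {
    # harmonic-toy force series at 21 lambda points (exact OU sampling)
    k_A <- 1; k_B <- 4; gamma <- 1; beta <- 1; dt <- 0.05
    lams <- seq(0, 1, length.out = 21L)
    for (i in seq_along(lams)) {
      k <- (1 - lams[i]) * k_A + lams[i] * k_B
      a <- exp(-k * dt / gamma)
      sdst <- sqrt(1 / (beta * k))
      x <- as.numeric(filter(rnorm(n_samples, sd = sdst * sqrt(1 - a^2)),
                             a, "recursive", init = rnorm(1, sd = sdst)))
      dhdl <- 0.5 * (k_B - k_A) * x^2
      f <- file.path(outdir, sprintf("harmonic_dhdl_%02d.xvg", i - 1L))
      write_xvg(cbind(seq_len(n_samples) * dt, dhdl), f,
                labels = "dH/dlambda",
                comments = sprintf("harmonic toy, lambda = %.3f", lams[i]),
                force = TRUE)
      written <- c(written, f)
    }
    # synthetic 2D channel metric field: cheap row at lambda_1 = 0.5
    l1 <- seq(0, 1, by = 0.25)
    l2 <- seq(0, 1, by = 0.25)
    grid <- as.matrix(expand.grid(lambda1 = l1, lambda2 = l2))
    np <- nrow(grid)
    val <- array(0, c(np, 2, 2))
    for (r in seq_len(np)) {
      cheap <- 0.05 + 4 * (grid[r, 1] - 0.5)^2
      val[r, , ] <- diag(c(cheap, cheap)) + 0.01
    }
    met <- metric_estimate(grid, val, estimator = "diffusion")
    f <- file.path(outdir, "channel_field.csv")
    write_metric_csv(met, f, force = TRUE)
    written <- c(written, f)
    # Crooks-consistent Gaussian work samples: dG = 1, sigma = 1
    dG <- 1; sig <- 1; n <- 5000L
    wf <- rnorm(n, mean = dG + sig^2 / 2, sd = sig)
    wr <- rnorm(n, mean = -dG + sig^2 / 2, sd = sig)
    f <- file.path(outdir, "crooks_work.csv")
    df <- data.frame(forward = wf, reverse = wr)
    write.table(format(df, digits = 17, trim = TRUE), f, sep = ",",
                row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    # minimal XVG example
    f <- file.path(outdir, "example.xvg")
    writeLines(c("# example series",
                 "@    xaxis  label \"Time\"",
                 "@ s0 legend \"dH/dlambda\"",
                 "0.0 1.5", "0.1 1.25", "0.2 1.75"), f)
    written <- c(written, f)
  })
  invisible(written)
}
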