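#' Toy alchemical systems
#'
#' An `alch_system` bundles a Hamiltonian `H(x; lambda)` together with its
#' analytic generalized-force components `dH/dlambda^mu` and spatial gradient.
#' The endpoint contract holds for every system: `lambda = 0` (all components)
#' gives the state-A Hamiltonian and `lambda = 1` the state-B Hamiltonian.
#'
#' Systems are backed by compiled kernels; the closures stored in the object
#' simply call into them, so R-level and sampler-level evaluations agree
#' exactly.
#'
#' @name alch_system
#' @return an object of class `alch_system` with fields
#'   `kind`, `n_lambda_dims`, `dim`, `x0` (a reference configuration) and
#'   callables `energy(x, lambda)`, `dHdlambda(x, lambda)`,
#'   `gradient(x, lambda)`.
NULL

new_alch_system <- function(kind, kernel_id, params, dim, n_lambda_dims, x0,
                            extra = list()) {
  force(kernel_id); force(params)
  sys <- c(list(
    kind = kind, kernel_id = kernel_id, params = params, dim = dim,
    n_lambda_dims = n_lambda_dims, x0 = x0,
    energy = function(x, lambda)
      cpp_energy(kernel_id, params, as_coords(x), as.numeric(lambda)),
    dHdlambda = function(x, lambda)
      cpp_dhdl(kernel_id, params, as_coords(x), as.numeric(lambda)),
    gradient = function(x, lambda)
      cpp_gradient(kernel_id, params, as_coords(x), as.numeric(lambda))),
    extra)
  class(sys) <- c(paste0(kind, "_system"), "alch_system")
  sys
}

#' @export
print.alch_system <- function(x, ...) {
  cat(sprintf("alch_system '%s': %d coordinate(s), %d lambda dimension(s)\n",
              x$kind, x$dim, x$n_lambda_dims))
  invisible(x)
}

#' Harmonic toy system
#'
#' `n_oscillators` independent particles in a harmonic well whose spring
#' constant is linearly interpolated,
#' `k(lambda) = (1 - lambda) k_A + lambda k_B`. The free energy difference
#' is known in closed form, `dG = n ln(k_B / k_A) / (2 beta)`, which makes
#' this the package's main analytic oracle. More oscillators emulate the
#' extensivity of real systems: energy gaps between neighboring lambda
#' ensembles grow with `n`, narrowing the ensemble overlap and localizing
#' the expanded-ensemble lambda walk.
#'
#' @param k_A,k_B spring constants of the end states (> 0).
#' @param n_oscillators number of independent oscillators (default 1).
#' @return an `alch_system` (see [alch_system]).
#' @examples
#' sys <- harmonic_system(1, 4)
#' harmonic_free_energy(sys, thermo_params())  # log(4)/2
#' @export
harmonic_system <- function(k_A = 1, k_B = 4, n_oscillators = 1L) {
  stopifnot(k_A > 0, k_B > 0, n_oscillators >= 1)
  n <- as.integer(n_oscillators)
  new_alch_system("harmonic", 1L, c(k_A, k_B, n), dim = n,
                  n_lambda_dims = 1L, x0 = rep(0, n),
                  extra = list(k_A = k_A, k_B = k_B, n_oscillators = n))
}

#' Closed-form free energy difference of the harmonic toy
#'
#' `dG = ln(k_B / k_A) / (2 beta)`, the log ratio of Gaussian partition
#' functions. Swapping the end states negates the result.
#'
#' @param system a [harmonic_system()].
#' @param thermo a [thermo_params()].
#' @return the free energy difference G_B - G_A (energy units).
#' @export
harmonic_free_energy <- function(system, thermo = thermo_params()) {
  stopifnot(inherits(system, "harmonic_system"))
  thermo <- as_thermo(thermo)
  system$n_oscillators * log(system$k_B / system$k_A) / (2 * thermo$beta)
}

#' Exact ensemble average of dH/dlambda for the harmonic toy
#'
#' `<dH/dlambda>_lambda = (k_B - k_A) / (2 beta k(lambda))`, the Gaussian
#' average of `(k_B - k_A) x^2 / 2`. Its lambda integral equals
#' [harmonic_free_energy()].
#'
#' @param system a [harmonic_system()].
#' @param lam coupling parameter(s) in \[0, 1\]; vectorized.
#' @param thermo a [thermo_params()].
#' @return the mean generalized-force magnitude at each `lam`.
#' @export
harmonic_mean_gradient <- function(system, lam, thermo = thermo_params()) {
  stopifnot(inherits(system, "harmonic_system"), all(lam >= 0), all(lam <= 1))
  thermo <- as_thermo(thermo)
  k <- (1 - lam) * system$k_A + lam * system$k_B
  system$n_oscillators * (system$k_B - system$k_A) / (2 * thermo$beta * k)
}

# closed-form metric profiles for the overdamped harmonic toy (OU process):
# friction g(lam) = (kB-kA)^2 gamma / (4 beta^2 k^3),
# Fisher-Rao g(lam) = (kB-kA)^2 / (2 beta^2 k^2)
harmonic_friction_exact <- function(system, lam, gamma = 1,
                                    thermo = thermo_params()) {
  thermo <- as_thermo(thermo)
  k <- (1 - lam) * system$k_A + lam * system$k_B
  system$n_oscillators * (system$k_B - system$k_A)^2 * gamma /
    (4 * thermo$beta^2 * k^3)
}

harmonic_fisher_rao_exact <- function(system, lam, thermo = thermo_params()) {
  thermo <- as_thermo(thermo)
  k <- (1 - lam) * system$k_A + lam * system$k_B
  system$n_oscillators * (system$k_B - system$k_A)^2 /
    (2 * thermo$beta^2 * k^2)
}

#' Two-dimensional micro-solvation toy system
#'
#' `n_solvent` Lennard-Jones particles in a periodic 2D square box plus one
#' solute whose interactions with the solvent are switched on through a
#' soft-core pair potential (state A: ideal-gas solute; state B: fully
#' coupled LJ + charge-like `q/r` term). Minimum-image convention with a
#' cutoff at half the box length; no long-range correction.
#'
#' @param n_solvent number of solvent particles (<= 64).
#' @param box box edge length.
#' @param epsilon_ss,sigma_ss solvent-solvent LJ parameters.
#' @param epsilon_solute,sigma_solute solute-solvent LJ parameters (state B).
#' @param charge solute-solvent charge product (state B).
#' @param alpha,p soft-core parameters.
#' @return an `alch_system`; the reference configuration `x0` places the
#'   particles on a square lattice.
#' @export
micro_solvation_system <- function(n_solvent = 16, box = 5,
                                   epsilon_ss = 1, sigma_ss = 1,
                                   epsilon_solute = 1, sigma_solute = 1,
                                   charge = 0.5, alpha = 0.5, p = 1L) {
  stopifnot(n_solvent >= 1, n_solvent <= 64, box > 2 * sigma_ss)
  params <- c(n_solvent, box, epsilon_ss, sigma_ss, epsilon_solute,
              sigma_solute, charge, alpha, p)
  # lattice start: solute in the middle of a cell, solvent on a square grid
  side <- ceiling(sqrt(n_solvent + 1))
  spacing <- box / side
  idx <- seq_len(n_solvent + 1) - 1
  gx <- (idx %% side + 0.5) * spacing
  gy <- (idx %/% side + 0.5) * spacing
  x0 <- as.numeric(rbind(gx, gy))
  new_alch_system("micro_solvation", 2L, params,
                  dim = 2L * (n_solvent + 1L), n_lambda_dims = 1L, x0 = x0,
                  extra = list(n_solvent = n_solvent, box = box))
}

#' Two-component lambda toy system
#'
#' A tethered particle with two independent coupling dimensions
#' `lambda = (lambda_coulomb, lambda_other)`: `lambda_other` switches a
#' soft-core Lennard-Jones term on, `lambda_coulomb` scales a charge-like
#' `q/r` term through a nonlinear schedule `q(lambda_c)` whose derivative is
#' proportional to `1 + a (2 lambda_c - 1)^2`. Because the generalized force
#' conjugate to `lambda_coulomb` is `q'(lambda_c)/r`, its fluctuations dip
#' sharply at `lambda_c = 0.5`, carving a low-metric channel across the 2D
#' lambda plane. The construction is synthetic: it emulates the qualitative
#' shape of ligand-mutation metric landscapes, not any particular molecule.
#'
#' @param k_tether,r0 tether spring constant and rest position.
#' @param epsilon,sigma soft-core LJ parameters of the `lambda_other` leg.
#' @param q1 full charge-term magnitude at `lambda_c = 1`.
#' @param channel_strength the `a` parameter; larger values deepen the
#'   channel at `lambda_c = 0.5`.
#' @param alpha,p soft-core parameters.
#' @return an `alch_system` with `n_lambda_dims = 2`.
#' @export
two_lambda_system <- function(k_tether = 5, r0 = 1.5, epsilon = 1, sigma = 1,
                              q1 = 2, channel_strength = 24,
                              alpha = 0.5, p = 1L) {
  stopifnot(k_tether > 0, r0 > 0, sigma > 0, channel_strength >= 0)
  params <- c(k_tether, r0, epsilon, sigma, q1, channel_strength, alpha, p)
  new_alch_system("two_lambda", 3L, params, dim = 1L, n_lambda_dims = 2L,
                  x0 = r0,
                  extra = list(q1 = q1, channel_strength = channel_strength))
}

#' Build a lambda grid for a system
#'
#' For a 1D system this is `n` equidistant scalars in \[0, 1\]; for 2D
#' systems the grid follows a [lambda_path()] (each row one lambda vector).
#'
#' @param n_points number of grid points.
#' @param n_dims number of lambda dimensions.
#' @return a numeric matrix with `n_points` rows and `n_dims` columns.
#' @export
lambda_grid <- function(n_points, n_dims = 1L) {
  stopifnot(n_points >= 1)
  matrix(rep(seq(0, 1, length.out = n_points), n_dims), ncol = n_dims)
}

as_lambda_matrix <- function(lambda, n_dims) {
  if (is.matrix(lambda)) {
    stopifnot(ncol(lambda) == n_dims)
    return(lambda)
  }
  stopifnot(n_dims == 1L)
  matrix(as.numeric(lambda), ncol = 1L)
}
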