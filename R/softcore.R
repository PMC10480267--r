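#' Soft-core pair potential parameters
#'
#' Describes a pair interaction that is alchemically transformed from state A
#' to state B using the Beutler-style soft-core scheme with a shared
#' lambda-dependent distance function for the Lennard-Jones and Coulomb
#' components:
#' \deqn{V_{sc}(r) = (1-\lambda) V^A(r_A) + \lambda V^B(r_B)}
#' \deqn{r_A = (\alpha \sigma_A^6 \lambda^p + r^6)^{1/6}, \quad
#'       r_B = (\alpha \sigma_B^6 (1-\lambda)^p + r^6)^{1/6}}
#' where \eqn{V^X(r) = 4\epsilon_X[(\sigma_X/r)^{12} - (\sigma_X/r)^6] + q_X/r}.
#'
#' @param sigma_A,sigma_B Lennard-Jones length parameters (> 0).
#' @param epsilon_A,epsilon_B Lennard-Jones well depths (>= 0).
#' @param charge_A,charge_B charge products (energy x length units).
#' @param alpha soft-core parameter (>= 0); 0.5 is the recommended value.
#' @param p soft-core lambda exponent, 1 or 2; 1 is the usual choice.
#' @return an object of class `softcore_pair`.
#' @examples
#' pair <- softcore_pair(1, 1, 1, 1)
#' softcore_pair_energy(0, 0.5, pair)  # finite at r = 0: soft core
#' @export
softcore_pair <- function(sigma_A = 1, sigma_B = 1, epsilon_A = 1,
                          epsilon_B = 1, charge_A = 0, charge_B = 0,
                          alpha = 0.5, p = 1L) {
  stopifnot(sigma_A > 0, sigma_B > 0, epsilon_A >= 0, epsilon_B >= 0,
            alpha >= 0, p %in% c(1L, 2L))
  structure(list(sigma_A = sigma_A, sigma_B = sigma_B,
                 epsilon_A = epsilon_A, epsilon_B = epsilon_B,
                 charge_A = charge_A, charge_B = charge_B,
                 alpha = alpha, p = as.integer(p)),
            class = "softcore_pair")
}

# plain (hard-core) LJ + Coulomb state potential; r may be a vector
state_potential <- function(r, epsilon, sigma, charge) {
  out <- numeric(length(r))
  zero <- r <= 0
  if (any(zero) && (epsilon != 0 || charge != 0))
    stop("singular configuration: r = 0 with a non-empty state potential")
  rr <- r[!zero]
  sr6 <- (sigma / rr)^6
  out[!zero] <- 4 * epsilon * (sr6^2 - sr6) + charge / rr
  out
}

state_potential_deriv <- function(r, epsilon, sigma, charge) {
  if (epsilon == 0 && charge == 0) return(numeric(length(r)))
  sr6 <- (sigma / r)^6
  4 * epsilon * (-12 * sr6^2 + 6 * sr6) / r - charge / r^2
}

#' Soft-core distance function
#'
#' \eqn{r_{sc} = (\alpha \sigma^6 \lambda_f^p + r^6)^{1/6}}. The lambda factor
#' is \eqn{\lambda} for the state-A distance and \eqn{1-\lambda} for state B.
#'
#' @param r particle-particle distance (>= 0); vectorized.
#' @param sigma Lennard-Jones length parameter (> 0).
#' @param lambda_factor coupling factor in \[0, 1\].
#' @param alpha soft-core alpha (default 0.5).
#' @param p soft-core exponent (default 1).
#' @return the soft-core modified distance, same length as `r`.
#' @export
softcore_distance <- function(r, sigma, lambda_factor, alpha = 0.5, p = 1L) {
  if (any(r < 0)) stop("r must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(all(lambda_factor >= 0), all(lambda_factor <= 1))
  (alpha * sigma^6 * lambda_factor^p + r^6)^(1 / 6)
}

#' Soft-core pair energy
#'
#' Evaluates the soft-core transformed pair potential at coupling `lam`, with
#' both the Lennard-Jones and Coulomb components of each state evaluated at
#' that state's soft-core distance. At `lam = 0` the result is exactly the
#' state-A potential, at `lam = 1` exactly state B.
#'
#' @param r distance (>= 0); vectorized.
#' @param lam coupling parameter in \[0, 1\].
#' @param pair a [softcore_pair()].
#' @return energy (reduced units), same length as `r`.
#' @export
softcore_pair_energy <- function(r, lam, pair) {
  stopifnot(inherits(pair, "softcore_pair"), lam >= 0, lam <= 1)
  if (any(r < 0)) stop("r must be non-negative")
  rA <- softcore_distance(r, pair$sigma_A, lam, pair$alpha, pair$p)
  rB <- softcore_distance(r, pair$sigma_B, 1 - lam, pair$alpha, pair$p)
  (1 - lam) * state_potential(rA, pair$epsilon_A, pair$sigma_A, pair$charge_A) +
    lam * state_potential(rB, pair$epsilon_B, pair$sigma_B, pair$charge_B)
}

#' Analytic derivative of the soft-core pair energy with respect to lambda
#'
#' Includes the lambda dependence through the soft-core distances
#' \eqn{r_A(\lambda)} and \eqn{r_B(\lambda)} (chain rule). With `alpha = 0`
#' this reduces to \eqn{V^B(r) - V^A(r)} (linear interpolation).
#'
#' @inheritParams softcore_pair_energy
#' @return dV/dlambda, same length as `r`.
#' @export
softcore_dVdlambda <- function(r, lam, pair) {
  stopifnot(inherits(pair, "softcore_pair"), lam >= 0, lam <= 1)
  if (any(r < 0)) stop("r must be non-negative")
  a <- pair$alpha
  p <- pair$p
  rA <- softcore_distance(r, pair$sigma_A, lam, a, p)
  rB <- softcore_distance(r, pair$sigma_B, 1 - lam, a, p)
  VA <- state_potential(rA, pair$epsilon_A, pair$sigma_A, pair$charge_A)
  VB <- state_potential(rB, pair$epsilon_B, pair$sigma_B, pair$charge_B)
  out <- -VA + VB
  # d r_A / d lambda = alpha sigma_A^6 p lambda^(p-1) / (6 r_A^5)
  if (a > 0) {
    dA <- a * pair$sigma_A^6 * p * lam^(p - 1) / (6 * rA^5)
    dB <- -a * pair$sigma_B^6 * p * (1 - lam)^(p - 1) / (6 * rB^5)
    dVA <- state_potential_deriv(rA, pair$epsilon_A, pair$sigma_A, pair$charge_A)
    dVB <- state_potential_deriv(rB, pair$epsilon_B, pair$sigma_B, pair$charge_B)
    out <- out + (1 - lam) * dVA * dA + lam * dVB * dB
  }
  out
}
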