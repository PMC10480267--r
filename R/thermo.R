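#' Thermodynamic parameters
#'
#' The package works in reduced units with `k_B = 1` by default, so
#' `beta = 1 / temperature`. All energies are in units of `k_B T` at
#' `temperature = 1`.
#'
#' @param temperature temperature in energy units (`k_B = 1`); must be > 0.
#' @param k_B Boltzmann constant in the chosen unit system (default 1).
#' @return an object of class `thermo_params` with fields `temperature`,
#'   `beta` and `k_B`.
#' @examples
#' th <- thermo_params()          # beta = 1
#' thermo_params(temperature = 2) # beta = 0.5
#' @export
thermo_params <- function(temperature = 1, k_B = 1) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0, k_B > 0)
  structure(list(temperature = temperature, beta = 1 / (k_B * temperature),
                 k_B = k_B),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("thermo_params: T = %g, beta = %g (k_B = %g)\n",
              x$temperature, x$beta, x$k_B))
  invisible(x)
}

as_thermo <- function(x) {
  if (inherits(x, "thermo_params")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermo_params(temperature = x))
  stop("expected a 'thermo_params' object")
}

#' Configuration of a system
#'
#' A thin container for the coordinates (and optionally momenta) of a toy
#' system. Most package functions accept a bare numeric vector as well.
#'
#' @param coordinates numeric vector of positions; all entries must be finite.
#' @param momenta optional numeric vector of the same length.
#' @return an object of class `configuration`.
#' @export
configuration <- function(coordinates, momenta = NULL) {
  coordinates <- as.numeric(coordinates)
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (!is.null(momenta)) {
    momenta <- as.numeric(momenta)
    if (length(momenta) != length(coordinates) || !all(is.finite(momenta)))
      stop("momenta must be finite and match coordinates in length")
  }
  structure(list(coordinates = coordinates, momenta = momenta),
            class = "configuration")
}

as_coords <- function(x) {
  if (inherits(x, "configuration")) x$coordinates else as.numeric(x)
}
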