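#' Thermal state
#'
#' Bundle a simulation temperature with the inverse temperature
#' \eqn{\beta = 1/(k_B T)} that defines all Boltzmann factors used by the
#' work-based free-energy estimators. Energies are kJ/mol, so
#' \eqn{k_B = 0.008314462618} kJ mol\eqn{^{-1}} K\eqn{^{-1}} and \eqn{\beta}
#' has units mol/kJ.
#'
#' @param temperature Temperature in kelvin; must be a single positive value.
#'   Defaults to 298 K, the temperature the simulations and titrations are
#'   run at.
#' @return An object of class `thermo_state` with fields `temperature`
#'   (kelvin) and `beta` (mol/kJ).
#' @examples
#' th <- make_thermo(298)
#' th$beta # ~0.4036 mol/kJ
#' @export
make_thermo <- function(temperature = 298) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop_param("temperature must be a single finite value > 0 K")
  }
  structure(
    list(temperature = as.numeric(temperature),
         beta = 1 / (.kB * as.numeric(temperature))),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("Thermal state: T = %g K, beta = %.6f mol/kJ\n",
              x$temperature, x$beta))
  invisible(x)
}

as_thermo <- function(x) {
  if (inherits(x, "thermo_state")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(make_thermo(x))
  stop_param("expected a thermo_state or a temperature in kelvin")
}

#' Redox estimate
#'
#' A midpoint/redox potential in millivolts with its standard error and the
#' estimator that produced it.
#'
#' @param potential Potential in mV.
#' @param std_error Standard error in mV (non-negative, or `NA` if the
#'   estimator does not define one).
#' @param method Label of the producing estimator.
#' @param n_forward,n_backward Sample counts behind the estimate.
#' @return An object of class `redox_estimate`.
#' @export
redox_estimate <- function(potential, std_error = NA_real_, method = "cb",
                           n_forward = NA_integer_, n_backward = NA_integer_) {
  if (!is.na(std_error) && std_error < 0) {
    stop_param("std_error must be >= 0")
  }
  structure(
    list(potential = as.numeric(potential),
         std_error = as.numeric(std_error),
         method = as.character(method),
         n_forward = as.integer(n_forward),
         n_backward = as.integer(n_backward)),
    class = "redox_estimate"
  )
}

#' @export
print.redox_estimate <- function(x, ...) {
  se <- if (is.na(x$std_error)) "NA" else sprintf("%.2f", x$std_error)
  cat(sprintf("Redox potential [%s]: %.2f +/- %s mV (n_fwd = %s, n_bwd = %s)\n",
              x$method, x$potential, se, x$n_forward, x$n_backward))
  invisible(x)
}

#' Convert a reduction free energy to a redox potential
#'
#' Applies \eqn{\Delta G = -nFE} with \eqn{F = 96485.3} C/mol
#' (96.4853 kJ mol\eqn{^{-1}} V\eqn{^{-1}}): the potential is
#' \eqn{E = -\Delta G/(nF)}, reported in millivolts, and the standard error
#' is scaled by the same positive factor.
#'
#' @param delta_g Reduction free energy in kJ/mol.
#' @param std_error Standard error of `delta_g` in kJ/mol (>= 0 or `NA`).
#' @param n_electrons Number of electrons transferred (>= 1); the proteins
#'   modelled here transfer one.
#' @param method,n_forward,n_backward Metadata carried into the result.
#' @return A [redox_estimate] in mV.
#' @examples
#' delta_g_to_potential(-9.64853)$potential # +100 mV
#' @export
delta_g_to_potential <- function(delta_g, std_error = NA_real_, n_electrons = 1,
                                 method = "cb", n_forward = NA_integer_,
                                 n_backward = NA_integer_) {
  if (!is.numeric(n_electrons) || length(n_electrons) != 1L ||
      !is.finite(n_electrons) || n_electrons < 1) {
    stop_param("n_electrons must be a single value >= 1")
  }
  if (!is.na(std_error) && std_error < 0) stop_param("std_error must be >= 0")
  scale <- 1000 / (n_electrons * .FARADAY_KJ_PER_V) # kJ/mol -> mV
  redox_estimate(
    potential = -delta_g * scale,
    std_error = if (is.na(std_error)) NA_real_ else std_error * scale,
    method = method, n_forward = n_forward, n_backward = n_backward
  )
}

#' Convert a redox potential back to a reduction free energy
#'
#' Inverse of [delta_g_to_potential()]: \eqn{\Delta G = -nFE}.
#'
#' @param potential Potential in mV, or a [redox_estimate].
#' @param std_error Standard error in mV (ignored when a [redox_estimate] is
#'   supplied).
#' @param n_electrons Number of electrons transferred (>= 1).
#' @return A list with `delta_g` and `std_error`, both kJ/mol.
#' @export
potential_to_delta_g <- function(potential, std_error = NA_real_, n_electrons = 1) {
  if (inherits(potential, "redox_estimate")) {
    std_error <- potential$std_error
    potential <- potential$potential
  }
  if (!is.numeric(n_electrons) || length(n_electrons) != 1L ||
      !is.finite(n_electrons) || n_electrons < 1) {
    stop_param("n_electrons must be a single value >= 1")
  }
  scale <- n_electrons * .FARADAY_KJ_PER_V / 1000 # mV -> kJ/mol
  list(delta_g = -potential * scale,
       std_error = if (is.na(std_error)) NA_real_ else std_error * scale)
}
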