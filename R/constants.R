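#' Physical constants for voltage-dependent rate evaluation
#'
#' Bundles the Faraday constant, the gas constant and the absolute
#' temperature used to form the reduced membrane potential
#' \eqn{\varphi(V) = V F / (R T)}, the dimensionless voltage that every
#' voltage-dependent transition rate is expressed in.
#'
#' Oocyte recordings are performed at room temperature; the default
#' temperature is 293.15 K (20 degrees C).  Within the 19-23 degrees C band
#' typical of such experiments, \eqn{\varphi} changes by less than 2%.
#'
#' @param temperature_K Absolute temperature in kelvin.  Must be positive.
#' @param faraday Faraday constant in C mol^-1.
#' @param gas_constant Molar gas constant in J mol^-1 K^-1.
#'
#' @return An object of class `iks_constants`: a list with elements `F`,
#'   `R` and `T`.
#' @examples
#' phys_constants()
#' reduced_potential(40, phys_constants())
#' @export
phys_constants <- function(temperature_K = 293.15,
                           faraday = 96485.33212,
                           gas_constant = 8.314462618) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    abort("`temperature_K` must be a single positive finite number.",
          class = "iksim_invalid_input")
  }
  if (!is.finite(faraday) || faraday <= 0 ||
      !is.finite(gas_constant) || gas_constant <= 0) {
    abort("`faraday` and `gas_constant` must be positive finite numbers.",
          class = "iksim_invalid_input")
  }
  structure(list(F = faraday, R = gas_constant, T = temperature_K),
            class = "iks_constants")
}

#' Reduced membrane potential
#'
#' Computes \eqn{\varphi(V) = V F / (R T)} with the membrane voltage given
#' in mV (converted internally to volts).  \eqn{\varphi} is dimensionless.
#'
#' @param voltage_mV Membrane voltage(s) in mV.  Must be finite.
#' @param constants A [phys_constants()] object.
#'
#' @return Numeric vector of reduced potentials, same length as
#'   `voltage_mV`.
#' @export
reduced_potential <- function(voltage_mV, constants = phys_constants()) {
  stopifnot(inherits(constants, "iks_constants"))
  if (!is.numeric(voltage_mV) || !all(is.finite(voltage_mV))) {
    abort("`voltage_mV` must be finite numeric.", class = "iksim_invalid_input")
  }
  (voltage_mV / 1000) * constants$F / (constants$R * constants$T)
}

#' @export
print.iks_constants <- function(x, ...) {
  cat(sprintf("<iks_constants> F = %.5f C/mol, R = %.9f J/mol/K, T = %.2f K\n",
              x$F, x$R, x$T))
  invisible(x)
}
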