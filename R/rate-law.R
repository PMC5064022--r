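#' Exponential voltage-dependent rate law
#'
#' A transition rate of the form
#' \eqn{k(V) = a \exp(z \varphi(V))}, where `a` is the base rate at 0 mV
#' (in s^-1), `z` is the effective charge (valence) coupling the
#' transition to the reduced membrane potential \eqn{\varphi = VF/RT}, and
#' `z = 0` gives a voltage-independent rate.
#'
#' @param amplitude Base rate `a` in s^-1; must be non-negative.
#' @param charge Effective valence `z` (dimensionless).  Default 0.
#'
#' @return An object of class `iks_rate_law`.
#' @examples
#' alpha1 <- rate_law(1, 0.47)
#' evaluate_rate(alpha1, 40)
#' @export
rate_law <- function(amplitude, charge = 0) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude < 0) {
    abort("`amplitude` must be a single non-negative finite number (s^-1).",
          class = "iksim_invalid_input")
  }
  if (!is.numeric(charge) || length(charge) != 1L || !is.finite(charge)) {
    abort("`charge` must be a single finite number.",
          class = "iksim_invalid_input")
  }
  structure(list(amplitude = amplitude, charge = charge),
            class = "iks_rate_law")
}

#' Evaluate a rate law at a membrane voltage
#'
#' @param law A [rate_law()] object.
#' @param voltage_mV Membrane voltage(s) in mV; must be finite.
#' @param constants A [phys_constants()] object.
#'
#' @return Rate(s) in s^-1, strictly positive whenever `amplitude > 0`.
#' @export
evaluate_rate <- function(law, voltage_mV, constants = phys_constants()) {
  stopifnot(inherits(law, "iks_rate_law"))
  phi <- reduced_potential(voltage_mV, constants)
  law$amplitude * exp(law$charge * phi)
}

#' @export
print.iks_rate_law <- function(x, ...) {
  if (x$charge == 0) {
    cat(sprintf("<iks_rate_law> %g s^-1 (voltage independent)\n", x$amplitude))
  } else {
    cat(sprintf("<iks_rate_law> %g * exp(%g phi) s^-1\n", x$amplitude, x$charge))
  }
  invisible(x)
}
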