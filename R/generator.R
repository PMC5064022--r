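#' Generator (Q) matrix of a scheme at a fixed voltage
#'
#' Standard master-equation construction: off-diagonal entry `(i, j)` is
#' the rate of the `i -> j` transition evaluated at `voltage_mV` (0 when
#' absent); each diagonal entry is the negative sum of the rest of its
#' row, so every row sums to zero.
#'
#' @param scheme An `iks_scheme`.
#' @param voltage_mV Membrane voltage in mV (single finite value).
#' @return A square numeric matrix (s^-1) with state labels as dimnames.
#' @examples
#' build_generator(iks_scheme(), 0)
#' @export
build_generator <- function(scheme, voltage_mV) {
  stopifnot(inherits(scheme, "iks_scheme"))
  if (!is.numeric(voltage_mV) || length(voltage_mV) != 1L ||
      !is.finite(voltage_mV)) {
    abort("`voltage_mV` must be a single finite number.",
          class = "iksim_invalid_input")
  }
  labels <- scheme$states$state
  n <- length(labels)
  Q <- matrix(0, n, n, dimnames = list(labels, labels))
  tr <- scheme$transitions
  phi <- reduced_potential(voltage_mV, scheme$constants)
  rates <- tr$amplitude * exp(tr$charge * phi)
  if (any(!is.finite(rates))) {
    abort("Non-finite transition rate at this voltage.",
          class = "iksim_invalid_input")
  }
  Q[cbind(match(tr$from, labels), match(tr$to, labels))] <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary occupancy distribution at a fixed voltage
#'
#' Solves `p Q = 0` subject to `sum(p) = 1`, the equilibrium occupancy
#' the channel population relaxes to when held at `voltage_mV`
#' indefinitely (e.g. at the holding potential before a protocol starts).
#'
#' @param scheme An `iks_scheme`.
#' @param voltage_mV Membrane voltage in mV.
#' @return Named probability vector (sums to 1, entries in \[0, 1\]).
#' @examples
#' steady_state(iks_scheme(), -80)
#' @export
steady_state <- function(scheme, voltage_mV) {
  Q <- build_generator(scheme, voltage_mV)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  qrA <- qr(A)
  if (qrA$rank < n) {
    abort("No unique steady state: generator is reducible/singular.",
          class = "iksim_no_unique_steady_state")
  }
  p <- qr.solve(A, c(rep(0, n), 1))
  p[p < 0 & p > -1e-9] <- 0
  if (any(p < 0)) {
    abort("Steady-state solve produced negative probabilities.",
          class = "iksim_numeric_error")
  }
  p <- p / sum(p)
  resid <- max(abs(p %*% Q))
  if (resid > 1e-8) {
    abort(sprintf("Steady-state residual too large (%.3g).", resid),
          class = "iksim_numeric_error")
  }
  stats::setNames(p, rownames(Q))
}
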