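# Occupancy propagation under the master equation dp/dt = p Q at constant
# voltage.  The propagator is the matrix exponential, computed once per
# (scheme, voltage) via eigendecomposition of Q and evaluated lazily on any
# time grid; if the decomposition is ill-conditioned (defective generator)
# propagation falls back to a stiff ODE integrator (deSolve::lsoda).

make_propagator <- function(Q) {
  eg <- eigen(Q)
  V <- eg$vectors
  ok <- TRUE
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) {
    ok <- FALSE
  } else {
    err <- max(Mod(V %*% Vinv - diag(nrow(Q))))
    if (!is.finite(err) || err > 1e-8) ok <- FALSE
  }
  list(Q = Q, values = eg$values, V = V, Vinv = Vinv, diagonalizable = ok)
}

# States reachable from the support of p0 along positive-rate edges.
# Columns outside this set are structural zeros of the solution and are
# pinned to exactly 0, so zero-rate edges (e.g. a binding extension at
# zero ligand) reproduce the reduced dynamics exactly.
reachable_states <- function(Q, p0) {
  n <- nrow(Q)
  seen <- p0 > 0
  queue <- which(seen)
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    succ <- which(Q[i, ] > 0 & seq_len(n) != i & !seen)
    seen[succ] <- TRUE
    queue <- c(queue, succ)
  }
  seen
}

# p0: probability row vector; times: vector of offsets >= 0.
# Returns a length(times) x n matrix of occupancies.
propagate_times <- function(prop, p0, times) {
  n <- nrow(prop$Q)
  if (prop$diagonalizable) {
    w <- as.vector(p0 %*% prop$V)                       # 1 x n (complex)
    E <- exp(outer(times, prop$values))                 # nt x n
    P <- Re(E %*% (w * prop$Vinv))
  } else {
    deriv <- function(t, p, parms) list(as.vector(p %*% prop$Q))
    ord <- order(times)
    tt <- times[ord]
    grid <- if (tt[1] > 0) c(0, tt) else tt
    sol <- deSolve::lsoda(y = as.vector(p0), times = grid, func = deriv,
                          rtol = 1e-10, atol = 1e-12)
    P <- unname(sol[match(tt, grid), -1, drop = FALSE])
    P <- P[order(ord), , drop = FALSE]
  }
  reach <- reachable_states(prop$Q, p0)
  if (!all(reach)) P[, !reach] <- 0
  guard_probabilities(P)
}

# Clip roundoff-scale negative occupancies and renormalize each row; any
# larger violation is a genuine solver failure and raises an error.
guard_probabilities <- function(P, tol = 1e-9) {
  if (any(!is.finite(P))) {
    abort("Propagation produced non-finite occupancies.",
          class = "iksim_numeric_error")
  }
  if (any(P < -tol) || any(P > 1 + tol)) {
    abort(sprintf("Occupancy outside [0, 1] beyond tolerance (min %.3g, max %.3g).",
                  min(P), max(P)),
          class = "iksim_numeric_error")
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Propagate occupancies at constant voltage
#'
#' Solves the master equation \eqn{dp/dt = p Q} at a fixed membrane
#' voltage from the initial occupancy `p0`, returning the occupancy at
#' every sample time from 0 to `duration` in steps of `dt`.  The solution
#' is exact (matrix exponential via eigendecomposition) for each output
#' time; a stiff ODE integrator is used only if the generator is
#' numerically defective.
#'
#' @param scheme An `iks_scheme`.
#' @param p0 Initial probability vector over the scheme's states (ordered
#'   as in `scheme$states`, or named); must sum to 1 within 1e-9.
#' @param voltage_mV Membrane voltage in mV.
#' @param duration Duration in seconds (>= 0).  `duration = 0` returns
#'   `p0` unchanged.
#' @param dt Output sampling interval in seconds (> 0).
#'
#' @return An `iks_occupancy` tibble with columns `time_s`, `voltage_mV`
#'   and one occupancy column per state; every row sums to 1.
#' @examples
#' p0 <- steady_state(iks_scheme(), -80)
#' propagate(iks_scheme(), p0, 40, duration = 1, dt = 0.01)
#' @export
propagate <- function(scheme, p0, voltage_mV, duration, dt = 1e-3) {
  stopifnot(inherits(scheme, "iks_scheme"))
  n <- n_states(scheme)
  if (length(p0) != n || any(!is.finite(p0)) || abs(sum(p0) - 1) > 1e-9 ||
      any(p0 < -1e-12)) {
    abort("`p0` must be a probability vector over the scheme's states.",
          class = "iksim_invalid_input")
  }
  if (!is.null(names(p0)) && all(scheme$states$state %in% names(p0))) {
    p0 <- p0[scheme$states$state]
  }
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration < 0) {
    abort("`duration` must be a single non-negative number (s).",
          class = "iksim_invalid_input")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number (s).",
          class = "iksim_invalid_input")
  }
  times <- if (duration == 0) 0 else seq(0, duration, by = dt)
  if (duration > 0 && times[length(times)] < duration - dt * 1e-6) {
    times <- c(times, duration)
  }
  prop <- make_propagator(build_generator(scheme, voltage_mV))
  P <- propagate_times(prop, as.numeric(p0), times)
  new_occupancy(times, voltage_mV, P, scheme)
}

new_occupancy <- function(times, voltage_mV, P, scheme) {
  colnames(P) <- scheme$states$state
  out <- tibble::as_tibble(as.data.frame(P))
  out <- dplyr::bind_cols(
    tibble::tibble(time_s = times,
                   voltage_mV = rep_len(voltage_mV, length(times))),
    out)
  structure(out,
            class = c("iks_occupancy", class(out)),
            states = scheme$states$state,
            conducting = scheme$states$state[scheme$states$conducting])
}

#' Total open probability of an occupancy trace
#'
#' Sums the occupancy columns of the scheme's conducting states at each
#' time point.
#'
#' @param trace An `iks_occupancy` (from [propagate()]).
#' @param scheme The `iks_scheme` the trace was generated from.
#' @return Numeric vector in \[0, 1\], one value per row of `trace`.
#' @export
open_probability <- function(trace, scheme) {
  stopifnot(inherits(trace, "iks_occupancy"), inherits(scheme, "iks_scheme"))
  if (!all(scheme$states$state %in% names(trace))) {
    abort("Trace columns do not match scheme states.",
          class = "iksim_invalid_input")
  }
  cond <- scheme$states$state[scheme$states$conducting]
  if (!length(cond)) return(rep(0, nrow(trace)))
  rowSums(as.matrix(trace[, cond, drop = FALSE]))
}
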