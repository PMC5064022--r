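# Shared fixtures and oracles, all built in code.

# Two-state toy scheme A -> B (rate a), B -> A (rate b); B conducts.
two_state_scheme <- function(a = 2, b = 1, charge_a = 0, charge_b = 0) {
  gating_scheme(
    states = tibble::tibble(state = c("A", "B"),
                            conducting = c(FALSE, TRUE)),
    transitions = tibble::tibble(
      label = c("f", "r"), from = c("A", "B"), to = c("B", "A"),
      amplitude = c(a, b), charge = c(charge_a, charge_b)),
    name = "two-state")
}

# Single non-conducting state; used with the binding extension.
one_state_scheme <- function() {
  gating_scheme(
    states = tibble::tibble(state = "S", conducting = FALSE),
    transitions = tibble::tibble(label = character(), from = character(),
                                 to = character(), amplitude = numeric(),
                                 charge = numeric()),
    name = "one-state")
}

# Independent explicit-Euler integrator for dp/dt = p Q at constant V,
# keeping every `keep_every`-th step (plus t = 0).
euler_propagate <- function(scheme, p0, voltage_mV, duration, dt,
                            keep_every = 1000L) {
  Q <- build_generator(scheme, voltage_mV)
  M <- diag(nrow(Q)) + Q * dt
  n_steps <- round(duration / dt)
  n_keep <- floor(n_steps / keep_every)
  keep <- matrix(NA_real_, n_keep + 1L, nrow(Q))
  keep[1L, ] <- p0
  p <- as.numeric(p0)
  k <- 1L
  for (i in seq_len(n_steps)) {
    p <- as.vector(p %*% M)
    if (i %% keep_every == 0L) {
      k <- k + 1L
      keep[k, ] <- p
    }
  }
  list(times = seq(0, by = dt * keep_every, length.out = n_keep + 1L),
       P = keep)
}

occupancy_matrix <- function(trace) {
  as.matrix(trace[, attr(trace, "states"), drop = FALSE])
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
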