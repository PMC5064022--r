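#' Macroscopic-current simulation settings
#'
#' Ohmic current synthesis: `I(t) = Gmax * Popen(t) * (V(t) - Erev)`,
#' with `Gmax` in uS, voltages in mV and the current reported in uA.
#' With the default K+ reversal of -90 mV (typical for ~4 mM external
#' K+), tail currents at -120 mV are inward (negative) while test-pulse
#' currents at depolarized voltages are outward (positive).  Normalized
#' analyses (tail activation curves, fractional inhibition) are
#' independent of `Gmax`.
#'
#' @param gmax_uS Maximal macroscopic conductance in uS (> 0).
#' @param erev_mV Reversal potential in mV (between -150 and 0 for
#'   K+-like conditions).
#' @return An `iks_settings` list.
#' @export
simulation_settings <- function(gmax_uS = 1, erev_mV = -90) {
  if (!is.numeric(gmax_uS) || gmax_uS <= 0) {
    abort("`gmax_uS` must be positive.", class = "iksim_invalid_input")
  }
  if (!is.numeric(erev_mV) || erev_mV <= -150 || erev_mV >= 0) {
    abort("`erev_mV` must lie in (-150, 0) mV.",
          class = "iksim_invalid_input")
  }
  structure(list(gmax_uS = gmax_uS, erev_mV = erev_mV),
            class = "iks_settings")
}

#' Simulate a noiseless voltage-clamp recording
#'
#' Drives the gating scheme through every sweep of the protocol and
#' synthesizes the macroscopic current
#' `I = Gmax * Popen * (V - Erev) / 1000` (uS x mV -> nA, reported in
#' uA).  The initial condition is the steady state at the protocol's
#' holding potential (or `p0` if supplied); between sweeps the occupancy
#' either re-equilibrates or carries over according to the protocol's
#' `reset` flag.
#'
#' @param scheme An `iks_scheme` with at least one conducting state.
#' @param protocol An `iks_protocol`.
#' @param settings An [simulation_settings()] object.
#' @param p0 Optional initial probability vector (defaults to the
#'   holding-potential steady state).
#'
#' @return An `iks_recording` tibble with columns `sweep_id`, `time_s`
#'   (within sweep), `voltage_mV`, `current_uA`, `popen`, `segment`
#'   (role), and a `metadata` attribute recording scheme, protocol,
#'   settings, noise and seed provenance.
#' @examples
#' rec <- simulate_recording(iks_scheme(), preset_protocol("fig9"))
#' @export
simulate_recording <- function(scheme, protocol,
                               settings = simulation_settings(),
                               p0 = NULL) {
  stopifnot(inherits(scheme, "iks_scheme"), inherits(protocol, "iks_protocol"),
            inherits(settings, "iks_settings"))
  if (!any(scheme$states$conducting)) {
    abort("Scheme has no conducting state; no current can be synthesized.",
          class = "iksim_config_error")
  }
  dt <- protocol_dt(protocol)
  reset <- protocol_reset(protocol)
  hold <- protocol_holding(protocol)
  p_hold <- if (is.null(p0)) {
    steady_state(scheme, hold)
  } else {
    if (length(p0) != n_states(scheme) || abs(sum(p0) - 1) > 1e-9) {
      abort("`p0` must be a probability vector over the scheme's states.",
            class = "iksim_invalid_input")
    }
    if (!is.null(names(p0)) && all(scheme$states$state %in% names(p0))) {
      p0 <- p0[scheme$states$state]
    }
    as.numeric(p0)
  }

  cond_idx <- which(scheme$states$conducting)
  props <- new.env(parent = emptyenv())
  get_prop <- function(v) {
    key <- format(v, digits = 15)
    if (is.null(props[[key]])) {
      props[[key]] <- make_propagator(build_generator(scheme, v))
    }
    props[[key]]
  }

  sweeps <- split(protocol, protocol$sweep_id)
  p_cur <- p_hold
  out <- vector("list", length(sweeps))
  for (si in seq_along(sweeps)) {
    seg_tbl <- sweeps[[si]]
    if (reset && si > 1L) p_cur <- p_hold
    t0 <- 0
    rows <- vector("list", nrow(seg_tbl) + 1L)
    # sweep starts with the occupancy at t = 0 under the first segment
    rows[[1L]] <- list(time = 0, v = seg_tbl$voltage_mV[[1L]],
                       role = seg_tbl$role[[1L]],
                       P = matrix(p_cur, nrow = 1))
    for (k in seq_len(nrow(seg_tbl))) {
      dur <- seg_tbl$duration_s[[k]]
      v <- seg_tbl$voltage_mV[[k]]
      offs <- seq(dt, dur, by = dt)
      if (!length(offs) || offs[length(offs)] < dur - dt * 1e-6) {
        offs <- c(offs, dur)
      }
      P <- propagate_times(get_prop(v), p_cur, offs)
      rows[[k + 1L]] <- list(time = t0 + offs, v = v,
                             role = seg_tbl$role[[k]], P = P)
      p_cur <- P[nrow(P), ]
      t0 <- t0 + dur
    }
    time_s <- unlist(lapply(rows, `[[`, "time"))
    volt <- unlist(lapply(rows, function(r) rep_len(r$v, length(r$time))))
    role <- unlist(lapply(rows, function(r) rep_len(r$role, length(r$time))))
    P <- do.call(rbind, lapply(rows, `[[`, "P"))
    popen <- rowSums(P[, cond_idx, drop = FALSE])
    out[[si]] <- tibble::tibble(
      sweep_id = seg_tbl$sweep_id[[1L]],
      time_s = time_s,
      voltage_mV = volt,
      current_uA = settings$gmax_uS * popen * (volt - settings$erev_mV) / 1000,
      popen = popen,
      segment = role)
  }
  new_recording(dplyr::bind_rows(out), scheme, protocol, settings,
                noise = NULL, seed = NULL)
}

new_recording <- function(data, scheme, protocol, settings, noise, seed) {
  metadata <- list(
    scheme_name = scheme$name,
    scheme_hash = rlang::hash(scheme[c("states", "transitions", "constants")]),
    scheme = scheme,
    protocol = protocol,
    settings = settings,
    noise = noise,
    seed = seed)
  structure(data,
            class = c("iks_recording", class(data)),
            metadata = metadata)
}

#' Recording provenance metadata
#' @param recording An `iks_recording`.
#' @return The metadata list (scheme, protocol, settings, noise, seed).
#' @export
recording_metadata <- function(recording) attr(recording, "metadata")

#' @export
print.iks_recording <- function(x, ...) {
  md <- recording_metadata(x)
  cat(sprintf("<iks_recording> scheme '%s', protocol '%s', %d sweep(s), %d samples\n",
              md$scheme_name, protocol_name(md$protocol),
              length(unique(x$sweep_id)), nrow(x)))
  NextMethod()
}
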