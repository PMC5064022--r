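#' Piecewise-constant voltage protocol
#'
#' A protocol is an ordered set of constant-voltage segments per sweep,
#' sampled at a fixed interval.  Segments carry a `role` label
#' (`"hold"`, `"test"`, `"tail"`, `"prepulse"`, `"inter"`) used by the
#' downstream analyses (exponential-fit windows, tail extraction).
#'
#' @param segments Data frame with columns `sweep_id` (integer),
#'   `segment_id` (integer, ordered within sweep), `role` (character),
#'   `duration_s` (> 0) and `voltage_mV`.
#' @param dt_s Sampling interval in seconds; must not exceed the shortest
#'   segment duration.
#' @param name Protocol name.
#' @param reset Logical: if `TRUE` (default) occupancies re-equilibrate to
#'   the holding-potential steady state between sweeps; if `FALSE`
#'   occupancy carries over sweep to sweep (repetitive/conditioning
#'   protocols, where the carry-over is the phenomenon of interest).
#' @param holding_mV Holding potential used for the initial condition;
#'   defaults to the voltage of the first segment.
#'
#' @return An `iks_protocol` tibble of segments with attributes `name`,
#'   `dt_s`, `reset`, `holding_mV`.
#' @seealso [preset_protocol()]
#' @export
voltage_protocol <- function(segments, dt_s = 1e-3, name = "protocol",
                             reset = TRUE, holding_mV = NULL) {
  segments <- tibble::as_tibble(segments)
  needed <- c("sweep_id", "segment_id", "role", "duration_s", "voltage_mV")
  stopifnot(all(needed %in% names(segments)))
  segments <- segments[needed]
  if (any(segments$duration_s <= 0) || any(!is.finite(segments$duration_s))) {
    abort("All segment durations must be positive.",
          class = "iksim_config_error")
  }
  if (dt_s <= 0 || dt_s > min(segments$duration_s) + 1e-12) {
    abort("`dt_s` must be positive and no longer than the shortest segment.",
          class = "iksim_config_error")
  }
  if (is.null(holding_mV)) holding_mV <- segments$voltage_mV[[1L]]
  structure(segments,
            class = c("iks_protocol", class(segments)),
            name = name, dt_s = dt_s, reset = reset, holding_mV = holding_mV)
}

#' @export
print.iks_protocol <- function(x, ...) {
  cat(sprintf("<iks_protocol> '%s': %d sweep(s), dt = %g s, holding %g mV, %s\n",
              attr(x, "name"), length(unique(x$sweep_id)), attr(x, "dt_s"),
              attr(x, "holding_mV"),
              if (attr(x, "reset")) "re-equilibrates between sweeps"
              else "occupancy carries over sweeps"))
  NextMethod()
}

protocol_dt <- function(protocol) attr(protocol, "dt_s")
protocol_name <- function(protocol) attr(protocol, "name")
protocol_reset <- function(protocol) attr(protocol, "reset")
protocol_holding <- function(protocol) attr(protocol, "holding_mV")

sweep_segments <- function(sweep_id, roles, durations, voltages) {
  tibble::tibble(sweep_id = as.integer(sweep_id),
                 segment_id = seq_along(roles),
                 role = roles, duration_s = durations, voltage_mV = voltages)
}

#' Standard voltage-clamp protocol presets
#'
#' The package's two-electrode voltage-clamp protocol library.  Available
#' presets (override any listed parameter via `...`; overrides are
#' explicit arguments, never silent changes):
#'
#' * `"fig9"` — holding -80 mV, 5 s steps from -40 to +60 mV in 20 mV
#'   increments, tail at -120 mV.  The protocol used for the simulated
#'   gating-modifier phenotype.  Parameters: `hold_mV` (-80), `hold_s`
#'   (1), `test_mV` (`seq(-40, 60, 20)`), `test_s` (5), `tail_mV` (-120),
#'   `tail_s` (1).
#' * `"activation_iv"` — 10 s pulses to -100 ... +60 mV in 20 mV
#'   increments from -80 mV; tails at -120 mV.  Parameters as for
#'   `"fig9"` with `test_mV = seq(-100, 60, 20)`, `test_s = 10`.
#' * `"deactivation_tails"` — 5 s prepulse to -20 mV, tails from -140 to
#'   -40 mV in 20 mV increments.  Parameters: `pre_mV` (-20), `pre_s`
#'   (5), `tail_mV` (`seq(-140, -40, 20)`), `tail_s` (2).
#' * `"repetitive_40"` — repeated 7 s pulses to +40 mV applied every 30 s
#'   from -80 mV; occupancy carries over between sweeps.  Parameters:
#'   `pulse_mV` (40), `pulse_s` (7), `interval_s` (23), `repeats` (10).
#' * `"rest_hold"` — a 4.5 min rest at -80 mV without pulsing followed by
#'   a 7 s test pulse to +40 mV (closed-state drug-access assay).
#'   Parameters: `rest_s` (270), `pulse_mV` (40), `pulse_s` (7).
#' * `"conditioning"` — control 5 s test pulse to 0 mV, then 1 min of
#'   300 ms subthreshold prepulses to -40 mV at `freq_Hz` (2 or 0.2),
#'   then the 5 s test pulse again; occupancy carries over
#'   (use-dependence assay).  Parameters: `freq_Hz` (2), `train_s` (60),
#'   `prepulse_mV` (-40), `prepulse_s` (0.3), `test_mV` (0), `test_s`
#'   (5), `hold_mV` (-80).
#'
#' @param name One of `"fig9"`, `"activation_iv"`, `"deactivation_tails"`,
#'   `"repetitive_40"`, `"rest_hold"`, `"conditioning"`.
#' @param ... Preset-specific overrides (see above).
#' @param dt_s Sampling interval in seconds (default 1 ms).
#'
#' @return An `iks_protocol`.
#' @examples
#' preset_protocol("fig9")
#' preset_protocol("conditioning", freq_Hz = 0.2)
#' @export
preset_protocol <- function(name, ..., dt_s = 1e-3) {
  known <- c("fig9", "activation_iv", "deactivation_tails",
             "repetitive_40", "rest_hold", "conditioning")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    abort(paste0("Unknown protocol preset; use one of: ",
                 paste(known, collapse = ", ")),
          class = "iksim_config_error")
  }
  builder <- switch(name,
    fig9 = function(hold_mV = -80, hold_s = 1, test_mV = seq(-40, 60, 20),
                    test_s = 5, tail_mV = -120, tail_s = 1) {
      segs <- purrr::imap(test_mV, function(v, i) {
        sweep_segments(i, c("hold", "test", "tail"),
                       c(hold_s, test_s, tail_s), c(hold_mV, v, tail_mV))
      })
      voltage_protocol(dplyr::bind_rows(segs), dt_s, "fig9",
                       reset = TRUE, holding_mV = hold_mV)
    },
    activation_iv = function(hold_mV = -80, hold_s = 1,
                             test_mV = seq(-100, 60, 20), test_s = 10,
                             tail_mV = -120, tail_s = 1) {
      segs <- purrr::imap(test_mV, function(v, i) {
        sweep_segments(i, c("hold", "test", "tail"),
                       c(hold_s, test_s, tail_s), c(hold_mV, v, tail_mV))
      })
      voltage_protocol(dplyr::bind_rows(segs), dt_s, "activation_iv",
                       reset = TRUE, holding_mV = hold_mV)
    },
    deactivation_tails = function(hold_mV = -80, hold_s = 1, pre_mV = -20,
                                  pre_s = 5, tail_mV = seq(-140, -40, 20),
                                  tail_s = 2) {
      segs <- purrr::imap(tail_mV, function(v, i) {
        sweep_segments(i, c("hold", "prepulse", "tail"),
                       c(hold_s, pre_s, tail_s), c(hold_mV, pre_mV, v))
      })
      voltage_protocol(dplyr::bind_rows(segs), dt_s, "deactivation_tails",
                       reset = TRUE, holding_mV = hold_mV)
    },
    repetitive_40 = function(hold_mV = -80, pulse_mV = 40, pulse_s = 7,
                             interval_s = 23, repeats = 10) {
      segs <- purrr::map(seq_len(repeats), function(i) {
        sweep_segments(i, c("test", "inter"),
                       c(pulse_s, interval_s), c(pulse_mV, hold_mV))
      })
      voltage_protocol(dplyr::bind_rows(segs), dt_s, "repetitive_40",
                       reset = FALSE, holding_mV = hold_mV)
    },
    rest_hold = function(hold_mV = -80, rest_s = 270, pulse_mV = 40,
                         pulse_s = 7) {
      voltage_protocol(
        sweep_segments(1, c("hold", "test"), c(rest_s, pulse_s),
                       c(hold_mV, pulse_mV)),
        dt_s, "rest_hold", reset = FALSE, holding_mV = hold_mV)
    },
    conditioning = function(hold_mV = -80, freq_Hz = 2, train_s = 60,
                            prepulse_mV = -40, prepulse_s = 0.3,
                            test_mV = 0, test_s = 5) {
      period <- 1 / freq_Hz
      if (period <= prepulse_s) {
        abort("Conditioning frequency too high for the prepulse duration.",
              class = "iksim_config_error")
      }
      n_pre <- floor(train_s * freq_Hz)
      roles <- c("hold", "test",
                 rep(c("prepulse", "inter"), n_pre),
                 "test")
      durs <- c(1, test_s,
                rep(c(prepulse_s, period - prepulse_s), n_pre),
                test_s)
      volts <- c(hold_mV, test_mV,
                 rep(c(prepulse_mV, hold_mV), n_pre),
                 test_mV)
      voltage_protocol(sweep_segments(1, roles, durs, volts),
                       dt_s, "conditioning", reset = FALSE,
                       holding_mV = hold_mV)
    })
  builder(...)
}

#' Count prepulses of a conditioning protocol
#' @param protocol An `iks_protocol`.
#' @return Integer number of segments with role `"prepulse"`.
#' @export
n_prepulses <- function(protocol) sum(protocol$role == "prepulse")
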