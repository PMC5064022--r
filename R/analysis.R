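# Recording-level analyses: end-of-pulse inhibition, tail-current
# activation curves, and per-sweep (de)activation kinetics.

segment_rows <- function(recording, role_wanted, sweep = NULL) {
  out <- dplyr::filter(recording, .data$segment == role_wanted)
  if (!is.null(sweep)) out <- dplyr::filter(out, .data$sweep_id %in% sweep)
  if (!nrow(out)) {
    abort(paste0("Recording has no '", role_wanted, "' segment."),
          class = "iksim_config_error")
  }
  out
}

#' End-of-pulse fractional inhibition
#'
#' Channel inhibition quantified as the reduction of current amplitude at
#' the end of a depolarizing test pulse:
#' `100 * (1 - I_drug / I_control)`, with each amplitude taken as the
#' mean over the final `window_s` (default 50 ms) of the designated
#' pulse.  The measure is invariant under common rescaling of both
#' recordings.
#'
#' @param control,drug `iks_recording`s acquired under matched protocols.
#' @param sweep Optional sweep id(s) to restrict to (default: all sweeps).
#' @param role Segment role of the pulse (default `"test"`).
#' @param window_s Averaging window before pulse end, in seconds.
#'
#' @return A tibble with columns `sweep_id`, `voltage_mV`,
#'   `i_control_uA`, `i_drug_uA`, `inhibition_pct`.
#' @export
end_pulse_inhibition <- function(control, drug, sweep = NULL, role = "test",
                                 window_s = 0.05) {
  stopifnot(inherits(control, "iks_recording"), inherits(drug, "iks_recording"))
  end_means <- function(rec) {
    segment_rows(rec, role, sweep) |>
      dplyr::group_by(.data$sweep_id) |>
      dplyr::summarise(
        voltage_mV = .data$voltage_mV[dplyr::n()],
        i_uA = mean(.data$current_uA[.data$time_s >
                                       max(.data$time_s) - window_s]),
        .groups = "drop")
  }
  a <- end_means(control)
  b <- end_means(drug)
  if (!identical(a$sweep_id, b$sweep_id) ||
      max(abs(a$voltage_mV - b$voltage_mV)) > 1e-9) {
    abort("Control and drug recordings do not share a matched protocol.",
          class = "iksim_config_error")
  }
  if (any(abs(a$i_uA) < 1e-12)) {
    abort("Control end-pulse current is ~0; inhibition ratio undefined.",
          class = "iksim_undefined_ratio")
  }
  tibble::tibble(sweep_id = a$sweep_id,
                 voltage_mV = a$voltage_mV,
                 i_control_uA = a$i_uA,
                 i_drug_uA = b$i_uA,
                 inhibition_pct = 100 * (1 - b$i_uA / a$i_uA))
}

#' Tail-current activation curve
#'
#' Extracts the initial tail-current amplitude of every sweep and
#' normalizes to the maximum across sweeps, giving the
#' activation-versus-prepulse-potential relation with maximum exactly 1.
#' "Initial" amplitude is, by default, the current at the first sample at
#' least `delay_s` (5 ms) after the tail step, letting the instantaneous
#' jump settle over a few sampling points; `method = "peak"` instead
#' takes the extreme value within `peak_window_s` of the step.
#'
#' @param recording An `iks_recording` whose protocol contains a tail
#'   segment.
#' @param method `"delayed"` (default) or `"peak"`.
#' @param delay_s Settling delay for `method = "delayed"`, seconds.
#' @param peak_window_s Search window for `method = "peak"`, seconds.
#'
#' @return A tibble with columns `sweep_id`, `voltage_mV` (the prepulse
#'   test potential), `tail_current_uA` and `activation` (normalized
#'   magnitude, max = 1).
#' @export
tail_activation_curve <- function(recording, method = c("delayed", "peak"),
                                  delay_s = 0.005, peak_window_s = 0.05) {
  stopifnot(inherits(recording, "iks_recording"))
  method <- match.arg(method)
  tails <- segment_rows(recording, "tail")
  pre_role <- if (any(recording$segment == "test")) "test" else "prepulse"
  prepulse <- segment_rows(recording, pre_role) |>
    dplyr::group_by(.data$sweep_id) |>
    dplyr::summarise(voltage_mV = .data$voltage_mV[[1L]], .groups = "drop")
  amp <- tails |>
    dplyr::group_by(.data$sweep_id) |>
    dplyr::summarise(
      tail_current_uA = {
        t0 <- min(.data$time_s)
        if (method == "delayed") {
          .data$current_uA[which(.data$time_s >= t0 + delay_s)[1L]]
        } else {
          w <- .data$current_uA[.data$time_s <= t0 + peak_window_s]
          w[which.max(abs(w))]
        }
      },
      .groups = "drop")
  out <- dplyr::left_join(prepulse, amp, by = "sweep_id")
  out$activation <- abs(out$tail_current_uA) / max(abs(out$tail_current_uA))
  out[c("sweep_id", "voltage_mV", "tail_current_uA", "activation")]
}

#' Per-sweep activation (or deactivation) time constants
#'
#' Fits a single exponential to the designated segment of every sweep and
#' returns the time constants.  For activation the default window skips
#' the first 200 ms of the test pulse, since the sigmoidal onset of the
#' slow delayed-rectifier current is only single-exponential at later
#' times; for tails (deactivation) the default skips 5 ms of settling.
#'
#' @param recording An `iks_recording`.
#' @param role Segment to fit: `"test"` (activation, default) or
#'   `"tail"` (deactivation).
#' @param skip_s Portion of the segment start excluded from the fit
#'   window (s).  Defaults to 0.2 for `"test"`, 0.005 for `"tail"`.
#' @param sweep Optional sweep id(s).
#'
#' @return A tibble with columns `sweep_id`, `voltage_mV` (of the fitted
#'   segment for tails, of the test segment for activation), `tau_s`,
#'   `converged`, and `tag`.
#' @export
segment_kinetics <- function(recording, role = c("test", "tail"),
                             skip_s = NULL, sweep = NULL) {
  stopifnot(inherits(recording, "iks_recording"))
  role <- match.arg(role)
  if (is.null(skip_s)) skip_s <- if (role == "test") 0.2 else 0.005
  tag <- if (role == "test") "tau_activation" else "tau_deactivation"
  rows <- segment_rows(recording, role, sweep)
  rows |>
    dplyr::group_by(.data$sweep_id) |>
    dplyr::group_map(function(d, key) {
      t0 <- min(d$time_s)
      fit <- exp_fit(tibble::tibble(time_s = d$time_s,
                                    signal = d$current_uA),
                     window = c(t0 + skip_s, max(d$time_s)), tag = tag)
      tibble::tibble(sweep_id = key$sweep_id,
                     voltage_mV = d$voltage_mV[[1L]],
                     tau_s = unname(fit$estimate[["tau"]]),
                     converged = fit$converged,
                     tag = tag)
    }) |>
    dplyr::bind_rows()
}

#' @rdname segment_kinetics
#' @export
activation_kinetics <- function(recording, skip_s = 0.2, sweep = NULL) {
  segment_kinetics(recording, "test", skip_s, sweep)
}

#' @rdname segment_kinetics
#' @export
deactivation_kinetics <- function(recording, skip_s = 0.005, sweep = NULL) {
  segment_kinetics(recording, "tail", skip_s, sweep)
}
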