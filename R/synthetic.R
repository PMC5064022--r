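# Seeded synthetic-data generators: noisy TEVC-like recordings, Hill
# concentration-response tables, and wash-in time courses.  Every
# generator is a pure function of (parameters, seed).

#' Recording noise model
#'
#' Additive Gaussian current noise, ohmic leak, and an optional slow
#' endogenous-current contaminant that activates (first-order, `tau_s`)
#' at voltages above a threshold — emulating the contamination of long
#' depolarizing pulses by endogenous oocyte conductances.  All
#' magnitudes are synthetic-fixture choices, not estimates of any real
#' recording.
#'
#' @param sigma_uA Additive Gaussian noise s.d. per sample (uA, >= 0).
#' @param g_leak_uS Ohmic leak conductance (uS, >= 0).
#' @param e_leak_mV Leak reversal potential (mV).
#' @param contaminant_uA Saturating amplitude of the slow contaminant
#'   (uA); 0 (default) disables it.
#' @param contaminant_tau_s Activation time constant of the contaminant.
#' @param contaminant_threshold_mV Voltage above which the contaminant
#'   activates.
#'
#' @return An `iks_noise` list.
#' @export
noise_model <- function(sigma_uA = 0.01, g_leak_uS = 0, e_leak_mV = 0,
                        contaminant_uA = 0, contaminant_tau_s = 2,
                        contaminant_threshold_mV = 40) {
  if (sigma_uA < 0 || g_leak_uS < 0) {
    abort("`sigma_uA` and `g_leak_uS` must be non-negative.",
          class = "iksim_invalid_input")
  }
  structure(list(sigma_uA = sigma_uA, g_leak_uS = g_leak_uS,
                 e_leak_mV = e_leak_mV, contaminant_uA = contaminant_uA,
                 contaminant_tau_s = contaminant_tau_s,
                 contaminant_threshold_mV = contaminant_threshold_mV),
            class = "iks_noise")
}

contaminant_current <- function(recording, noise) {
  if (noise$contaminant_uA == 0) return(rep(0, nrow(recording)))
  out <- numeric(nrow(recording))
  for (sw in split(seq_len(nrow(recording)), recording$sweep_id)) {
    above <- recording$voltage_mV[sw] > noise$contaminant_threshold_mV
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      idx <- sw[starts[r]:ends[r]]
      t_rel <- recording$time_s[idx] - recording$time_s[idx[1L]]
      out[idx] <- noise$contaminant_uA *
        (1 - exp(-t_rel / noise$contaminant_tau_s))
    }
  }
  out
}

#' Generate a noisy synthetic voltage-clamp recording
#'
#' Runs [simulate_recording()] and adds, per sample, ohmic leak
#' `g_leak * (V - E_leak) / 1000` (uA), the optional slow contaminant,
#' and Gaussian noise.  Deterministic for a fixed seed: the same
#' arguments always give bit-identical output, and with
#' `sigma_uA = 0`, `g_leak_uS = 0` and no contaminant the result equals
#' the noiseless simulation exactly.
#'
#' @param scheme,protocol,settings,p0 As in [simulate_recording()].
#' @param noise An [noise_model()].
#' @param seed Non-negative integer seed.
#'
#' @return An `iks_recording` whose metadata records the noise model and
#'   seed.
#' @export
synth_recording <- function(scheme, protocol,
                            settings = simulation_settings(),
                            noise = noise_model(), seed = 1, p0 = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 ||
      seed != floor(seed)) {
    abort("`seed` must be a non-negative integer.",
          class = "iksim_invalid_input")
  }
  rec <- simulate_recording(scheme, protocol, settings, p0 = p0)
  leak <- noise$g_leak_uS * (rec$voltage_mV - noise$e_leak_mV) / 1000
  contam <- contaminant_current(rec, noise)
  eps <- if (noise$sigma_uA > 0) {
    withr::with_seed(as.integer(seed),
                     stats::rnorm(nrow(rec), 0, noise$sigma_uA))
  } else {
    rep(0, nrow(rec))
  }
  rec$current_uA <- rec$current_uA + leak + contam + eps
  md <- attr(rec, "metadata")
  md$noise <- noise
  md$seed <- as.integer(seed)
  attr(rec, "metadata") <- md
  rec
}

#' Generate a synthetic Hill concentration-response table
#'
#' Replicate fractional responses `1 / (1 + (C / IC50)^H)` with
#' multiplicative Gaussian scatter `(1 + N(0, sigma_rel))`, clipped to
#' \[0, 1.1\].  Deterministic per seed.
#'
#' @param ic50_M Generating IC50 in mol/L (> 0).
#' @param hill Generating Hill coefficient (> 0).
#' @param concentrations_M Concentration grid in mol/L (default half-log
#'   steps from 10 nM to 10 uM).
#' @param sigma_rel Relative s.d. of replicate scatter (default 0.03).
#' @param n_replicates Replicates per concentration.
#' @param seed Non-negative integer seed.
#'
#' @return An `iks_dose_response` tibble with columns `concentration_M`,
#'   `replicate`, `response`, and attributes recording the generating
#'   parameters.
#' @examples
#' synth_dose_response(78.4e-9, 1, seed = 7)
#' @export
synth_dose_response <- function(ic50_M, hill,
                                concentrations_M = 10^seq(-8, -5, by = 0.5),
                                sigma_rel = 0.03, n_replicates = 5,
                                seed = 1) {
  if (!is.numeric(ic50_M) || ic50_M <= 0 || !is.numeric(hill) || hill <= 0) {
    abort("`ic50_M` and `hill` must be positive.",
          class = "iksim_invalid_input")
  }
  if (!length(concentrations_M) || any(concentrations_M <= 0)) {
    abort("`concentrations_M` must be a non-empty positive vector.",
          class = "iksim_invalid_input")
  }
  grid <- tidyr::expand_grid(concentration_M = concentrations_M,
                             replicate = seq_len(n_replicates))
  mu <- hill_response(grid$concentration_M, ic50_M, hill)
  resp <- if (sigma_rel > 0) {
    scatter <- withr::with_seed(as.integer(seed),
                                stats::rnorm(nrow(grid), 0, sigma_rel))
    pmin(pmax(mu * (1 + scatter), 0), 1.1)
  } else {
    mu
  }
  out <- dplyr::mutate(grid, response = resp)
  structure(out,
            class = c("iks_dose_response", class(out)),
            generating = list(ic50_M = ic50_M, hill = hill,
                              sigma_rel = sigma_rel, seed = as.integer(seed)))
}

#' Simulate drug wash-in time courses across concentrations
#'
#' For each ligand concentration, augments the scheme with the explicit
#' binding extension ([augment_with_binding()]), starts from the
#' drug-free steady state at the holding potential (drug applied at
#' t = 0 with zero bound occupancy), and pulses repetitively while
#' occupancy carries over sweeps.  End-of-pulse current amplitudes,
#' normalized to the first pulse, give the wash-in time series; a
#' single-exponential fit of that series gives `tau_inhibition` per
#' concentration.
#'
#' The pulse train defaults to 1 s pulses to +40 mV every `period_s`
#' (5 s) — denser than a classical 7 s/30 s inhibition protocol so that
#' wash-in rates spanning two decades of concentration remain resolvable
#' by the same train.  The number of pulses per concentration is chosen
#' as ~4 expected binding time constants (`1 / (kon C + koff)`), bounded
#' to \[20, 500\].
#'
#' @param scheme An unbound `iks_scheme`.
#' @param concentrations_M Positive ligand concentrations (mol/L).
#' @param kon,koff Binding rate constants (M^-1 s^-1, s^-1).
#' @param competent Binding-competent state labels.
#' @param bound_config Drug configuration of the bound copy.
#' @param hold_mV Holding potential (mV).
#' @param pulse_mV,pulse_s,period_s Pulse train parameters.
#' @param dt_s Sampling interval (default 10 ms; wash-in is slow).
#' @param noise An [noise_model()] applied to each recording.
#' @param seed Non-negative integer seed.
#' @param window_s End-of-pulse averaging window (s).
#'
#' @return An `iks_washin` list with elements `amplitudes` (tibble:
#'   `concentration_M`, `pulse`, `time_s`, `amplitude_uA`,
#'   `norm_amplitude`), `taus` (tibble: `concentration_M`, `tau_s`,
#'   `converged`) and `recordings` (named list of `iks_recording`).
#' @export
synth_washin <- function(scheme, concentrations_M,
                         kon = 1e4, koff = kon * 78.4e-9,
                         competent = c("C1", "C2", "C3", "C2s"),
                         bound_config = ac1_bound_config(),
                         hold_mV = -80, pulse_mV = 40, pulse_s = 1,
                         period_s = 5, dt_s = 0.01,
                         noise = noise_model(sigma_uA = 0), seed = 1,
                         window_s = 0.05) {
  if (any(concentrations_M < 0)) {
    abort("Concentrations must be non-negative.",
          class = "iksim_invalid_input")
  }
  p_free <- steady_state(scheme, hold_mV)
  res <- purrr::map(seq_along(concentrations_M), function(i) {
    conc <- concentrations_M[[i]]
    spec <- binding_spec(kon, koff, conc, competent, bound_config)
    aug <- augment_with_binding(scheme, spec)
    p0 <- c(unname(p_free), rep(0, n_states(scheme)))
    rate <- kon * conc + koff
    tau_expected <- if (rate > 0) 1 / rate else Inf
    repeats <- min(500L, max(20L, ceiling(4 * tau_expected / period_s)))
    protocol <- preset_protocol("repetitive_40", hold_mV = hold_mV,
                                pulse_mV = pulse_mV, pulse_s = pulse_s,
                                interval_s = period_s - pulse_s,
                                repeats = repeats, dt_s = dt_s)
    rec <- synth_recording(aug, protocol, noise = noise,
                           seed = seed + i - 1L, p0 = p0)
    amp <- segment_rows(rec, "test") |>
      dplyr::group_by(.data$sweep_id) |>
      dplyr::summarise(
        amplitude_uA = mean(.data$current_uA[.data$time_s >
                                               max(.data$time_s) - window_s]),
        .groups = "drop") |>
      dplyr::mutate(concentration_M = conc,
                    pulse = .data$sweep_id,
                    time_s = (.data$sweep_id - 1) * period_s + pulse_s,
                    norm_amplitude = .data$amplitude_uA /
                      .data$amplitude_uA[[1L]])
    fit <- if (conc > 0) {
      exp_fit(tibble::tibble(time_s = amp$time_s,
                             signal = amp$norm_amplitude),
              tag = "tau_inhibition")
    } else {
      NULL
    }
    list(recording = rec,
         amplitudes = amp[c("concentration_M", "pulse", "time_s",
                            "amplitude_uA", "norm_amplitude")],
         tau = tibble::tibble(
           concentration_M = conc,
           tau_s = if (is.null(fit)) NA_real_ else
             unname(fit$estimate[["tau"]]),
           converged = if (is.null(fit)) NA else fit$converged))
  })
  recordings <- purrr::map(res, "recording")
  names(recordings) <- paste0(format(concentrations_M, scientific = TRUE), "M")
  structure(list(
    amplitudes = dplyr::bind_rows(purrr::map(res, "amplitudes")),
    taus = dplyr::bind_rows(purrr::map(res, "tau")),
    recordings = recordings,
    kd_M = if (kon > 0) koff / kon else NA_real_),
    class = "iks_washin")
}

#' @export
print.iks_washin <- function(x, ...) {
  cat(sprintf("<iks_washin> %d concentration(s), Kd = %.3g M\n",
              nrow(x$taus), x$kd_M))
  print(x$taus)
  invisible(x)
}
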