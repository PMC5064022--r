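test_that("degenerate noise reproduces the noiseless simulation exactly", {
  s <- iks_scheme()
  p <- preset_protocol("fig9", test_mV = c(0, 40), dt_s = 5e-3)
  clean <- simulate_recording(s, p)
  synth <- synth_recording(s, p, noise = noise_model(sigma_uA = 0), seed = 9)
  expect_identical(clean$current_uA, synth$current_uA)
})

test_that("synthetic recordings are pure functions of their seed", {
  s <- iks_scheme()
  p <- preset_protocol("fig9", test_mV = 40, dt_s = 5e-3)
  nm <- noise_model(sigma_uA = 0.02, g_leak_uS = 0.05)
  r1 <- synth_recording(s, p, noise = nm, seed = 11)
  r2 <- synth_recording(s, p, noise = nm, seed = 11)
  r3 <- synth_recording(s, p, noise = nm, seed = 12)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false(identical(r1$current_uA, r3$current_uA))
  expect_equal(recording_metadata(r1)$seed, 11L)
})

test_that("ohmic leak shifts the current by g_leak * (V - E_leak)", {
  s <- iks_scheme()
  p <- preset_protocol("fig9", test_mV = 40, dt_s = 5e-3)
  base <- simulate_recording(s, p)
  leaky <- synth_recording(s, p,
                           noise = noise_model(sigma_uA = 0, g_leak_uS = 0.1,
                                               e_leak_mV = -10),
                           seed = 1)
  expect_equal(leaky$current_uA - base$current_uA,
               0.1 * (base$voltage_mV - (-10)) / 1000, tolerance = 1e-12)
  # a leak-only cell at V = E_leak carries zero mean current
  hold <- voltage_protocol(
    tibble::tibble(sweep_id = 1L, segment_id = 1L, role = "hold",
                   duration_s = 1, voltage_mV = -10))
  leak_only <- synth_recording(s, hold, simulation_settings(erev_mV = -10),
                               noise = noise_model(sigma_uA = 0,
                                                   g_leak_uS = 0.5,
                                                   e_leak_mV = -10),
                               seed = 1)
  expect_true(all(leak_only$current_uA == 0))
})

test_that("the slow contaminant activates only above its voltage threshold", {
  s <- iks_scheme()
  p <- preset_protocol("fig9", test_mV = c(20, 60), dt_s = 5e-3)
  base <- simulate_recording(s, p)
  cont <- synth_recording(
    s, p, noise = noise_model(sigma_uA = 0, contaminant_uA = 0.5,
                              contaminant_tau_s = 2,
                              contaminant_threshold_mV = 40),
    seed = 1)
  extra <- cont$current_uA - base$current_uA
  expect_true(all(extra[cont$voltage_mV <= 40] == 0))
  above <- extra[cont$voltage_mV > 40]
  expect_true(all(diff(above) >= 0))
  expect_equal(max(above), 0.5 * (1 - exp(-5 / 2)), tolerance = 1e-3)
})

test_that("synthetic dose-response tables follow the Hill equation", {
  tbl <- synth_dose_response(78.4e-9, 1, sigma_rel = 0, seed = 5)
  expect_equal(tbl$response,
               1 / (1 + (tbl$concentration_M / 78.4e-9)^1))
  at_ic50 <- synth_dose_response(1e-7, 2, concentrations_M = 1e-7,
                                 sigma_rel = 0, seed = 1)
  expect_true(all(at_ic50$response == 0.5))
  # seeded determinism and clipping
  n1 <- synth_dose_response(78.4e-9, 1, sigma_rel = 0.3, seed = 2)
  n2 <- synth_dose_response(78.4e-9, 1, sigma_rel = 0.3, seed = 2)
  expect_identical(n1$response, n2$response)
  expect_true(all(n1$response >= 0 & n1$response <= 1.1))
  expect_error(synth_dose_response(1e-7, 1, concentrations_M = numeric()),
               class = "iksim_invalid_input")
  expect_error(synth_dose_response(-1, 1), class = "iksim_invalid_input")
})

test_that("wash-in declines faster at higher ligand concentration", {
  w <- synth_washin(iks_scheme(), c(1e-6, 1e-5), kon = 1e4,
                    period_s = 5, pulse_s = 1, seed = 3)
  expect_true(all(w$taus$converged))
  expect_lt(w$taus$tau_s[2], w$taus$tau_s[1])
  # normalized amplitude starts at 1 and declines under drug
  amp1 <- dplyr::filter(w$amplitudes, concentration_M == 1e-5)
  expect_equal(amp1$norm_amplitude[1], 1)
  expect_lt(amp1$norm_amplitude[nrow(amp1)], 0.5)
})

test_that("zero concentration leaves the pulse train amplitude flat", {
  w0 <- synth_washin(iks_scheme(), 0, kon = 1e4, period_s = 5, pulse_s = 1,
                     seed = 3)
  amps <- w0$amplitudes$norm_amplitude
  expect_true(all(abs(amps - 1) < 0.05))
  expect_true(is.na(w0$taus$tau_s))
})
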