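rec_pair <- function(scale = 0.1) {
  p <- preset_protocol("fig9", test_mV = c(0, 40), dt_s = 5e-3)
  ctrl <- simulate_recording(iks_scheme(), p)
  drug <- ctrl
  drug$current_uA <- drug$current_uA * scale
  list(ctrl = ctrl, drug = drug)
}

test_that("end-pulse inhibition is the fractional amplitude reduction", {
  # 2.0 uA control vs 0.2 uA drug -> 90 % inhibition
  rp <- rec_pair(scale = 0.1)
  out <- end_pulse_inhibition(rp$ctrl, rp$drug)
  expect_equal(out$inhibition_pct, rep(90, 2), tolerance = 1e-12)
  # no drug effect -> 0 %
  same <- end_pulse_inhibition(rp$ctrl, rp$ctrl)
  expect_equal(same$inhibition_pct, rep(0, 2))
})

test_that("end-pulse inhibition is invariant under common rescaling", {
  rp <- rec_pair(scale = 0.25)
  base <- end_pulse_inhibition(rp$ctrl, rp$drug)
  ctrl2 <- rp$ctrl; drug2 <- rp$drug
  ctrl2$current_uA <- ctrl2$current_uA * 7.3
  drug2$current_uA <- drug2$current_uA * 7.3
  expect_equal(end_pulse_inhibition(ctrl2, drug2)$inhibition_pct,
               base$inhibition_pct, tolerance = 1e-12)
})

test_that("a near-zero control current makes the ratio undefined", {
  s <- iks_scheme()
  p <- voltage_protocol(
    tibble::tibble(sweep_id = 1L, segment_id = 1L, role = "test",
                   duration_s = 1, voltage_mV = -90))
  zero <- simulate_recording(s, p, simulation_settings(erev_mV = -90))
  expect_error(end_pulse_inhibition(zero, zero),
               class = "iksim_undefined_ratio")
})

test_that("tail activation curves are normalized to a maximum of 1", {
  rec <- simulate_recording(iks_scheme(), preset_protocol("fig9", dt_s = 2e-3))
  curve <- tail_activation_curve(rec)
  expect_equal(max(curve$activation), 1)
  expect_true(all(curve$activation >= 0 & curve$activation <= 1))
  # activation grows with prepulse voltage
  expect_true(all(diff(curve$activation[order(curve$voltage_mV)]) > 0))
  # identical prepulses give identical (all-1) normalized tails
  rec_same <- simulate_recording(
    iks_scheme(), preset_protocol("fig9", test_mV = c(40, 40, 40, 40, 40),
                                  dt_s = 5e-3))
  expect_equal(tail_activation_curve(rec_same)$activation, rep(1, 5))
})

test_that("a missing tail segment is a configuration error", {
  rec <- simulate_recording(iks_scheme(),
                            preset_protocol("repetitive_40", repeats = 1,
                                            dt_s = 5e-3))
  expect_error(tail_activation_curve(rec), class = "iksim_config_error")
})

test_that("peak extraction finds the largest-magnitude early tail current", {
  rec <- simulate_recording(iks_scheme(), preset_protocol("fig9", dt_s = 2e-3))
  delayed <- tail_activation_curve(rec, method = "delayed")
  peak <- tail_activation_curve(rec, method = "peak")
  expect_equal(max(peak$activation), 1)
  # the peak magnitude can only exceed the post-settling sample
  expect_true(all(abs(peak$tail_current_uA) >=
                    abs(delayed$tail_current_uA) - 1e-12))
})

test_that("activation kinetics are slower under drug at strong depolarization", {
  p <- preset_protocol("fig9", test_mV = 40, dt_s = 5e-3)
  tau_free <- activation_kinetics(simulate_recording(iks_scheme("free"), p))
  tau_bound <- activation_kinetics(simulate_recording(iks_scheme("bound"), p))
  expect_true(tau_free$converged && tau_bound$converged)
  expect_gt(tau_bound$tau_s, tau_free$tau_s)
})
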