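test_that("current vanishes at the reversal potential", {
  s <- iks_scheme()
  p <- voltage_protocol(
    tibble::tibble(sweep_id = 1L, segment_id = 1L, role = "test",
                   duration_s = 1, voltage_mV = -90))
  rec <- simulate_recording(s, p, simulation_settings(erev_mV = -90))
  expect_true(all(rec$current_uA == 0))
})

test_that("current is linear in the maximal conductance", {
  s <- iks_scheme()
  p <- preset_protocol("fig9", test_mV = c(0, 40), dt_s = 5e-3)
  r1 <- simulate_recording(s, p, simulation_settings(gmax_uS = 1))
  r2 <- simulate_recording(s, p, simulation_settings(gmax_uS = 2))
  expect_identical(2 * r1$current_uA, r2$current_uA)
  expect_identical(r1$popen, r2$popen)
})

test_that("identical inputs give bit-identical recordings", {
  s <- iks_scheme("bound")
  p <- preset_protocol("fig9", test_mV = c(20, 60), dt_s = 5e-3)
  r1 <- simulate_recording(s, p)
  r2 <- simulate_recording(s, p)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("tail currents at -120 mV are inward under a K+-like reversal", {
  rec <- simulate_recording(iks_scheme(), preset_protocol("fig9", dt_s = 2e-3))
  tails <- dplyr::filter(rec, segment == "tail", sweep_id == 6)
  expect_true(all(tails$current_uA <= 0))
  expect_lt(min(tails$current_uA), -1e-4)
  # outward during strong depolarization
  test60 <- dplyr::filter(rec, segment == "test", sweep_id == 6)
  expect_gt(max(test60$current_uA), 0)
})

test_that("open probability sums conducting-state occupancies", {
  s <- iks_scheme()
  tr <- propagate(s, c(1, 0, 0, 0, 0, 0), -80, 0, 1e-3)
  expect_equal(open_probability(tr, s), 0)  # all occupancy closed
  tr2 <- propagate(s, c(0.2, 0.2, 0.1, 0.3, 0.2, 0), -80, 0, 1e-3)
  expect_equal(open_probability(tr2, s), 0.5)
  # monotone activation at +40 from rest in the drug-free scheme
  tr3 <- propagate(s, unname(steady_state(s, -80)), 40, 5, 0.01)
  po <- open_probability(tr3, s)
  expect_true(all(diff(po) > -1e-12))
  expect_true(all(po >= 0 & po <= 1))
})

test_that("drug binding reduces end-pulse current at strong depolarization", {
  p <- preset_protocol("fig9", test_mV = 60, dt_s = 5e-3)
  rf <- simulate_recording(iks_scheme("free"), p)
  rb <- simulate_recording(iks_scheme("bound"), p)
  end_free <- dplyr::filter(rf, segment == "test") |> dplyr::pull(current_uA)
  end_bound <- dplyr::filter(rb, segment == "test") |> dplyr::pull(current_uA)
  expect_lt(end_bound[length(end_bound)], end_free[length(end_free)])
})

test_that("a scheme without conducting states cannot be simulated", {
  s <- one_state_scheme()
  p <- voltage_protocol(
    tibble::tibble(sweep_id = 1L, segment_id = 1L, role = "test",
                   duration_s = 1, voltage_mV = 0))
  expect_error(simulate_recording(s, p), class = "iksim_config_error")
})
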