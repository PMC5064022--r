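test_that("the 5 s step preset is laid out as printed", {
  p <- preset_protocol("fig9")
  expect_equal(length(unique(p$sweep_id)), 6)
  tests <- dplyr::filter(p, role == "test")
  expect_equal(tests$voltage_mV, seq(-40, 60, 20))
  expect_true(all(tests$duration_s == 5))
  tails <- dplyr::filter(p, role == "tail")
  expect_true(all(tails$voltage_mV == -120))
  expect_equal(attr(p, "holding_mV"), -80)
  expect_true(attr(p, "reset"))
})

test_that("the activation IV preset spans -100 to +60 in 20 mV steps", {
  p <- preset_protocol("activation_iv")
  tests <- dplyr::filter(p, role == "test")
  expect_equal(nrow(tests), 9)
  expect_equal(tests$voltage_mV, seq(-100, 60, 20))
  expect_true(all(tests$duration_s == 10))
})

test_that("conditioning trains carry the arithmetic number of prepulses", {
  # 2 Hz for 1 min -> 120 prepulses of 300 ms at -40 mV
  p2 <- preset_protocol("conditioning", freq_Hz = 2)
  expect_equal(n_prepulses(p2), 120)
  pre <- dplyr::filter(p2, role == "prepulse")
  expect_true(all(pre$duration_s == 0.3))
  expect_true(all(pre$voltage_mV == -40))
  expect_equal(n_prepulses(preset_protocol("conditioning", freq_Hz = 0.2)), 12)
  expect_false(attr(p2, "reset"))
})

test_that("repetitive and rest presets carry occupancy over sweeps", {
  p <- preset_protocol("repetitive_40", repeats = 5)
  expect_equal(length(unique(p$sweep_id)), 5)
  expect_false(attr(p, "reset"))
  expect_equal(attr(p, "holding_mV"), -80)
  r <- preset_protocol("rest_hold")
  expect_equal(r$duration_s[r$role == "hold"], 270)
})

test_that("protocol validation enforces sampling and naming rules", {
  expect_error(preset_protocol("nope"), class = "iksim_config_error")
  segs <- tibble::tibble(sweep_id = 1L, segment_id = 1L, role = "test",
                         duration_s = 0.01, voltage_mV = 0)
  expect_error(voltage_protocol(segs, dt_s = 0.02),
               class = "iksim_config_error")
  expect_error(voltage_protocol(dplyr::mutate(segs, duration_s = 0)),
               class = "iksim_config_error")
  expect_error(preset_protocol("conditioning", freq_Hz = 4),
               class = "iksim_config_error")
})
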