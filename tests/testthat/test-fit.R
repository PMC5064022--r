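test_that("the Hill fitter recovers noise-free generating parameters", {
  tbl <- synth_dose_response(234e-9, 1, sigma_rel = 0, seed = 1)
  fit <- hill_fit(tbl)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$estimate[["IC50"]], 234e-9), 1e-6)
  expect_lt(rel_err(fit$estimate[["H"]], 1), 1e-6)
  # midpoint and zero-concentration limits of the fitted curve
  expect_equal(unname(predict(fit, fit$estimate[["IC50"]])), 0.5)
  expect_equal(unname(predict(fit, 1e-30)), 1, tolerance = 1e-6)
})

test_that("the Hill fit is invariant under concentration rescaling", {
  tbl <- synth_dose_response(78.4e-9, 1.3, sigma_rel = 0.02, seed = 3)
  f_M <- hill_fit(tbl)
  tbl_nM <- dplyr::mutate(tbl, concentration_M = concentration_M * 1e9)
  f_nM <- hill_fit(tbl_nM, ic50_bounds_M = c(1e-2, 1e6))
  expect_equal(f_nM$estimate[["IC50"]] / 1e9, f_M$estimate[["IC50"]],
               tolerance = 1e-6)
  expect_equal(f_nM$estimate[["H"]], f_M$estimate[["H"]], tolerance = 1e-6)
})

test_that("Hill fit input contracts are enforced", {
  expect_error(
    hill_fit(tibble::tibble(concentration_M = c(-1e-9, 1e-9, 1e-8),
                            response = c(1, 0.5, 0))),
    class = "iksim_invalid_input")
  expect_error(
    hill_fit(tibble::tibble(concentration_M = c(1e-9, 1e-8),
                            response = c(0.9, 0.2))),
    class = "iksim_invalid_input")
})

test_that("the Boltzmann fitter recovers noise-free parameters", {
  v <- seq(-100, 100, 10)
  y <- 0.05 + (0.95 - 0.05) / (1 + exp((12 - v) / 9))
  fit <- boltzmann_fit(tibble::tibble(voltage_mV = v, response = y))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$estimate[["v_half"]], 12), 1e-6)
  expect_lt(rel_err(fit$estimate[["k"]], 9), 1e-6)
  # value at V1/2 is the half-amplitude point
  expect_equal(unname(predict(fit, fit$estimate[["v_half"]])),
               (fit$estimate[["a_max"]] + fit$estimate[["a_min"]]) / 2)
  expect_error(
    boltzmann_fit(tibble::tibble(voltage_mV = c(-20, 0, 20, 40),
                                 response = c(0, 0.3, 0.7, 1))),
    class = "iksim_invalid_input")
})

test_that("the exponential fitter recovers noise-free parameters", {
  t <- seq(0, 3, by = 1e-3)
  y <- 2 + 3 * exp(-t / 0.5)
  fit <- exp_fit(tibble::tibble(time_s = t, signal = y))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate), c(2, 3, 0.5), tolerance = 1e-6)
  # y(tau) - A0 = A / e, the defining property of tau
  expect_equal(unname(predict(fit, 0.5) - fit$estimate[["A0"]]),
               unname(fit$estimate[["A"]]) / exp(1), tolerance = 1e-6)
  # window restriction uses only in-window rows
  fitw <- exp_fit(tibble::tibble(time_s = t, signal = y), window = c(1, 3))
  expect_equal(unname(fitw$estimate[["tau"]]), 0.5, tolerance = 1e-6)
})

test_that("a flat trace is flagged rather than fitted", {
  fit <- exp_fit(tibble::tibble(time_s = seq(0, 1, 0.01), signal = 1))
  expect_false(fit$converged)
  expect_identical(fit$tag, "flat trace")
})

test_that("the log-log fitter is exact on pure power laws", {
  conc <- 10^seq(-7, -5, length.out = 6)
  fit <- linear_log_fit(tibble::tibble(concentration_M = conc,
                                       tau_s = 1 / (1e4 * conc)))
  expect_equal(unname(fit$estimate[["m"]]), -1, tolerance = 1e-12)
  expect_equal(unname(fit$estimate[["b"]]), -4, tolerance = 1e-9)
  # duplicated points leave the OLS solution unchanged
  dup <- tibble::tibble(concentration_M = rep(conc, 2),
                        tau_s = rep(1 / (1e4 * conc), 2))
  expect_equal(coef(linear_log_fit(dup)), coef(fit))
  expect_error(
    linear_log_fit(tibble::tibble(concentration_M = c(1e-7, 1e-6),
                                  tau_s = c(10, 1))),
    class = "iksim_invalid_input")
})

test_that("tidy and glance expose broom-style summaries", {
  tbl <- synth_dose_response(78.4e-9, 1, sigma_rel = 0, seed = 1)
  fit <- hill_fit(tbl)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("IC50", "H"))
  gl <- glance(fit)
  expect_named(gl, c("family", "tag", "rss", "converged", "nobs"))
  expect_true(gl$converged)
})
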