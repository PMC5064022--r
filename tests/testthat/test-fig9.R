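# The full simulated gating-modifier phenotype report.  Built once here
# and reused across assertions (it simulates 12 sweeps at 1 ms sampling).
report <- reproduce_fig9()

test_that("the phenotype report reproduces the closed-state-stabilization signature", {
  expect_s3_class(report, "iks_fig9_report")
  expect_true(report$all_pass)
  expect_identical(report$rho_ratio, 100)
  # depolarizing shift of the activation curve
  expect_gt(report$v_half$delta_v_half_mV, 0)
  # both Boltzmann fits converged with sensible slope factors
  expect_true(report$fits$control$converged && report$fits$bound$converged)
  expect_gt(report$fits$control$estimate[["k"]], 0)
  # normalized tails peak at exactly 1 in both conditions
  tails <- report$tails
  expect_equal(max(tails$activation[tails$condition == "control"]), 1)
  expect_equal(max(tails$activation[tails$condition == "drug-bound"]), 1)
})

test_that("activation slows under drug where the stabilized state drains", {
  act <- report$activation_tau
  upper <- act[act$voltage_mV >= 20, ]
  expect_true(all(upper$tau_s_bound > upper$tau_s_control))
  # the slowing grows with depolarization over the drained range
  ratio <- upper$tau_s_bound / upper$tau_s_control
  expect_true(all(diff(ratio[order(upper$voltage_mV)]) > 0))
})

test_that("inhibition is relieved at higher potentials, deactivation spared", {
  relief <- report$inhibition[report$inhibition$voltage_mV >= 20, ]
  expect_true(all(diff(relief$inhibition_pct[order(relief$voltage_mV)]) < 0))
  expect_true(all(report$inhibition$inhibition_pct > 0))
  # relative deactivation change at -120 mV << relative activation change at +40
  d <- report$deactivation_tau
  rel_deact <- abs(d$tau_bound_s - d$tau_control_s) / d$tau_control_s
  a <- report$activation_tau
  rel_act <- with(a[a$voltage_mV == 40, ],
                  abs(tau_s_bound - tau_s_control) / tau_s_control)
  expect_lt(rel_deact, rel_act)
  expect_lt(rel_deact, 0.1)
})
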