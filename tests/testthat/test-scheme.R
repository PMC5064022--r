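test_that("the packaged IKs scheme has the expected structure", {
  s <- iks_scheme()
  expect_s3_class(s, "iks_scheme")
  expect_equal(s$states$state, c("C1", "C2", "C3", "O1", "O2", "C2s"))
  expect_equal(s$states$state[s$states$conducting], c("O1", "O2"))
  expect_equal(nrow(s$transitions), 10)
  # every rate finite at the extremes of the physiological range
  for (v in c(-200, 200)) {
    expect_true(all(is.finite(build_generator(s, v))))
  }
})

test_that("scheme validation rejects malformed graphs", {
  st <- tibble::tibble(state = c("A", "B"), conducting = c(FALSE, TRUE))
  expect_error(
    gating_scheme(st, tibble::tibble(
      label = c("x", "y"), from = c("A", "A"), to = c("B", "B"),
      amplitude = 1, charge = 0)),
    class = "iksim_config_error")  # duplicate ordered pair
  expect_error(
    gating_scheme(st, tibble::tibble(
      label = "x", from = "A", to = "Z", amplitude = 1, charge = 0)),
    class = "iksim_config_error")  # unknown state
  expect_error(
    gating_scheme(st, tibble::tibble(
      label = "x", from = "A", to = "A", amplitude = 1, charge = 0)),
    class = "iksim_config_error")  # self loop
  st3 <- tibble::tibble(state = c("A", "B", "C"),
                        conducting = c(FALSE, TRUE, FALSE))
  expect_error(
    gating_scheme(st3, tibble::tibble(
      label = "x", from = "A", to = "B", amplitude = 1, charge = 0)),
    class = "iksim_config_error")  # C disconnected
})

test_that("drug configuration overrides only the named transition", {
  s <- iks_scheme()
  expect_identical(apply_drug_config(s, drug_config())$transitions,
                   s$transitions)
  b <- apply_drug_config(s, ac1_bound_config())
  rho_free <- s$transitions$amplitude[s$transitions$label == "rho"]
  rho_bound <- b$transitions$amplitude[b$transitions$label == "rho"]
  expect_equal(rho_bound, 0.1)
  expect_identical(rho_free / rho_bound, 100)
  other <- b$transitions$label != "rho"
  expect_identical(b$transitions[other, ], s$transitions[other, ])
  # original untouched
  expect_equal(s$transitions$amplitude[s$transitions$label == "rho"], 10)
  expect_error(apply_drug_config(s, drug_config(nope = rate_law(1))),
               class = "iksim_config_error")
})

test_that("binding augmentation doubles the scheme with mass-action edges", {
  s <- iks_scheme()
  spec <- binding_spec(kon = 1e5, koff = 1e-2, concentration_M = 1e-6)
  aug <- augment_with_binding(s, spec)
  expect_equal(n_states(aug), 12)
  expect_equal(binding_kd(spec), 1e-7)
  on_edges <- aug$transitions[grepl("^on\\.", aug$transitions$label), ]
  expect_equal(nrow(on_edges), 4)
  expect_true(all(on_edges$amplitude == 1e5 * 1e-6))
  # the bound copy carries the slowed C2s exit
  expect_equal(
    aug$transitions$amplitude[aug$transitions$label == "rho.b"], 0.1)
  # conducting flags copied to the bound twin
  expect_equal(sum(aug$states$conducting), 4)
  expect_error(
    augment_with_binding(s, binding_spec(1e5, 1e-2, 1e-6,
                                         competent = "missing")),
    class = "iksim_config_error")
  expect_error(
    augment_with_binding(s, binding_spec(1e5, 1e-2, 1e-6,
                                         competent = character())),
    class = "iksim_config_error")
})

test_that("zero ligand concentration reproduces the unbound dynamics", {
  s <- iks_scheme()
  aug <- augment_with_binding(s, binding_spec(1e5, 1e-2, 0))
  p0 <- unname(steady_state(s, -80))
  tr_unbound <- propagate(s, p0, 40, 1, 0.01)
  tr_aug <- propagate(aug, c(p0, rep(0, 6)), 40, 1, 0.01)
  bound_cols <- paste0(s$states$state, ".b")
  expect_true(all(occupancy_matrix(tr_aug)[, bound_cols] == 0))
  expect_equal(occupancy_matrix(tr_aug)[, s$states$state],
               occupancy_matrix(tr_unbound), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("at C = Kd half the population is bound at equilibrium", {
  s <- one_state_scheme()
  spec <- binding_spec(kon = 1e6, koff = 1e-2, concentration_M = 1e-8,
                       competent = "S", bound_config = drug_config())
  aug <- augment_with_binding(s, spec)
  p <- steady_state(aug, -80)
  expect_equal(unname(p[["S.b"]]), 0.5, tolerance = 1e-12)
})

test_that("bound-copy occupancy rises monotonically during wash-in at rest", {
  s <- iks_scheme()
  aug <- augment_with_binding(s, binding_spec(1e4, 1e4 * 78.4e-9, 1e-6))
  p0 <- c(unname(steady_state(s, -80)), rep(0, 6))
  tr <- propagate(aug, p0, -80, 300, 1)
  bound_frac <- rowSums(
    occupancy_matrix(tr)[, paste0(s$states$state, ".b")])
  expect_true(all(diff(bound_frac) > -1e-12))
  expect_gt(bound_frac[length(bound_frac)], 0.5)
})
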