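# Calcium homeostasis: pumps, buffers, compartment coupling.

test_that("plasma-membrane flux balances at the basal pair and restores", {
  p <- calcium_params()
  expect_lt(abs(plasma_membrane_fluxes(0.06, 2000, p)), 1e-9)
  # zero cytosolic Ca: pumps silent, leak drives inward
  expect_gt(plasma_membrane_fluxes(0, 2000, p), 0)
  # above basal the net flux is strictly negative (restoring), monotone
  cas <- seq(0.07, 5, length.out = 40)
  net <- vapply(cas, plasma_membrane_fluxes, 0, ca_cleft = 2000, p = p)
  expect_true(all(net < 0))
  expect_true(all(diff(net) < 0))
})

test_that("buffers follow the binding isotherm at equilibrium", {
  p <- calcium_params()
  for (bn in names(p$buffers)) {
    b <- p$buffers[[bn]]
    net <- new_network()
    net <- add_species(net, c("Ca_cyt", "B", "CaB"), "cytosol",
                       c(0.5, b$total, 0))
    # clamp calcium: binding consumes B only (pseudo-first-order in Ca)
    net <- add_reaction(net, "on", c(B = -1, CaB = 1), law = "custom",
                        params = list(kon_b = b$kon),
                        formula = "kon_b * Ca_cyt * B")
    net <- add_reaction(net, "off", c(CaB = -1, B = 1),
                        law = "mass_action", params = c(k = b$kon * b$Kd))
    out <- simulate_network(net, c(0, 50, 100), atol = 1e-12)
    bound_frac <- unname(out[nrow(out), "CaB"]) / b$total
    expect_equal(bound_frac, 0.5 / (0.5 + b$Kd), tolerance = 1e-9)
  }
  rates <- buffer_derivatives(0, c(CaM = 25, CaN = 1, PKC = 1),
                              c(CaM = 0, CaN = 0, PKC = 0))
  expect_true(all(rates$net == 0))
})

test_that("buffering attenuates a calcium step transient", {
  mk <- function(with_buffer) {
    net <- new_network()
    net <- add_species(net, "Ca_cyt", "cytosol", 0.06)
    net <- add_reaction(net, "influx", c(Ca_cyt = 1), law = "custom",
                        params = list(jin = 2),
                        formula = "jin * (t >= 0.1 && t < 0.2)")
    net <- add_reaction(net, "clear", c(Ca_cyt = -1), law = "mass_action",
                        params = c(k = 10))
    if (with_buffer) {
      net <- add_species(net, c("B", "CaB"), "cytosol", c(25, 0))
      net <- add_reaction(net, "on", c(Ca_cyt = -1, B = -1, CaB = 1),
                          law = "mass_action", params = c(k = 50))
      net <- add_reaction(net, "off", c(CaB = -1, Ca_cyt = 1, B = 1),
                          law = "mass_action", params = c(k = 100))
    }
    max(simulate_network(net, seq(0, 0.5, by = 1e-3),
                         restart_at = c(0.1, 0.2))[, "Ca_cyt"])
  }
  expect_lt(mk(TRUE), mk(FALSE))
})

test_that("intercompartment exchange conserves amount and relaxes at the
           closed-form two-box rate", {
  fx <- make_fixture("two_box_exchange", k_ex = 0.005, c1 = 2, c2 = 0.5)
  net <- new_network()
  net <- add_species(net, c("X_psd", "X_cyt"), c("PSD", "cytosol"),
                     c(fx$c1, fx$c2))
  net <- add_reaction(net, "ex", c(X_psd = -1, X_cyt = 1), law = "custom",
                      params = list(kx = fx$k_ex / 0.002),
                      formula = "kx * (X_psd - X_cyt)", home = "PSD")
  out <- simulate_network(net, seq(0, 400, by = 2), atol = 1e-12)
  an <- fx$analytic(out[, "time"])
  expect_equal(out[, "X_psd"], an$c1, tolerance = 1e-6)
  expect_equal(out[, "X_cyt"], an$c2, tolerance = 1e-6)
  amount <- 0.002 * out[, "X_psd"] + 0.02 * out[, "X_cyt"]
  expect_lt(diff(range(amount)) / amount[1], 1e-9)

  flux <- intercompartment_exchange(2, 0.5, 0.005)
  expect_equal(flux$dpsd * 0.002 + flux$dcyt * 0.02, 0)
  expect_equal(intercompartment_exchange(1, 1, 0.005)$dpsd, 0)
})

test_that("buffer totals are conserved in the full model under stimulation", {
  res <- spine_calibration_run()
  ser <- res$series[seq(1, nrow(res$series), by = 200), ]
  for (bn in c("CaM", "CaN", "PKC")) for (sfx in c("cyt", "psd")) {
    tot <- ser[[paste0(bn, "_", sfx)]] + ser[[paste0("Ca", bn, "_", sfx)]]
    expect_lt(diff(range(tot)) / tot[1], 1e-8)
  }
})
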