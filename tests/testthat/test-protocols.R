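# Protocol construction, equilibration, trajectory simulation.

test_that("protocol event lists match their definitions", {
  expect_equal(make_protocol("single")$events$time, 0)
  expect_equal(make_protocol("burst4")$events$time, c(0, 0.01, 0.02, 0.03))

  tbs5 <- make_protocol("tbs5")$events$time
  expect_length(tbs5, 20)
  expect_equal(tbs5[seq(1, 20, by = 4)], seq(0, 0.8, by = 0.2))

  tbs9 <- make_protocol("tbs9")$events$time
  expect_length(tbs9, 36)
  expect_equal(tbs9[seq(1, 36, by = 4)], seq(0, 1.6, by = 0.2))

  tet <- make_protocol("tetanus", frequency = 100, duration = 1)$events$time
  expect_length(tet, 100)
  expect_equal(tet, seq(0, 0.99, by = 0.01))

  expect_error(make_protocol("nope"), "arg")
  expect_error(make_protocol("tetanus", frequency = -1), "frequency")
})

test_that("the assembled model equilibrates to the stated baselines", {
  base <- mglur_spine_baseline()
  b <- attr(base, "baselines")
  expect_equal(unname(b["Ca_cyt"]), 0.06, tolerance = 0.01)
  expect_equal(unname(b["IP3_cyt"]), 0.1, tolerance = 0.01)
  expect_equal(unname(b["Ca_cleft"]), 2000, tolerance = 0.01)
  expect_equal(unname(b["Ca_ER"]), 500, tolerance = 0.01)
})

test_that("the baseline is a fixed point and attracts perturbed states", {
  model <- mglur_spine_model()
  base <- mglur_spine_baseline()
  zero <- list(glu_mglur = function(t) 0, glu_psd = function(t) 0)
  out <- simulate_network(model$network, c(0, 50, 100), init = base,
                          inputs = zero)
  drift <- abs(out[nrow(out), -1] - base) / pmax(base, 1e-6)
  expect_lt(max(drift), 1e-6)

  # +/-20% perturbations relax back to the same resting concentrations for
  # the species pinned by pump/leak/production balances (species bound by
  # conservation laws, e.g. total receptor or G protein, necessarily settle
  # at values scaled with their perturbed totals)
  for (fac in c(0.8, 1.2)) {
    pert <- base * fac
    pert["Ca_cleft"] <- base[["Ca_cleft"]]   # clamped boundary reservoir
    # IP3R subunit occupancies are fractions whose sum is structurally
    # conserved; renormalise so the perturbed state satisfies the contract
    xs <- grep("^x[01]{3}$", names(pert))
    pert[xs] <- pert[xs] / sum(pert[xs])
    out2 <- simulate_network(model$network, c(0, 10000, 20000), init = pert,
                             inputs = zero)
    final <- out2[nrow(out2), -1]
    key <- c("Ca_cyt", "IP3_cyt", "Ca_ER")
    expect_lt(max(abs(final[key] - base[key]) / base[key]), 1e-3)
  }
})

test_that("an empty protocol leaves every series flat at baseline", {
  model <- mglur_spine_model()
  res <- run_protocol(model, release_events(numeric(0)), duration = 2,
                      baseline = mglur_spine_baseline())
  for (v in c("Ca_cyt", "IP3_cyt", "GaGTP"))
    expect_lt(diff(range(res$series[[v]])) /
                max(res$series[[v]][1], 1e-9), 1e-6)
})

test_that("the calibration protocol reproduces the spine calcium anchors", {
  res <- spine_calibration_run()
  s <- res$series
  peak <- max(s$Ca_cyt)
  expect_gt(peak, 0.18); expect_lt(peak, 0.22)   # ~200 nM
  fit <- fit_mono_exponential_decay(s$time, s$Ca_cyt, from = 0.08)
  expect_gt(fit$tau, 0.72); expect_lt(fit$tau, 0.88)  # ~800 ms
})

test_that("halving solver tolerances barely changes the reported metrics", {
  model <- mglur_spine_model()
  base <- mglur_spine_baseline()
  pr <- make_protocol("burst4")
  run_at <- function(rtol, atol) {
    m2 <- model
    m2$config$simulation$rtol <- rtol
    m2$config$simulation$atol <- atol
    res <- run_protocol(m2, pr, duration = 6, baseline = base)
    c(peak = max(res$series$Ca_cyt),
      auc = auc_riemann(res$series$time, res$series$Ca_cyt,
                        baseline = base[["Ca_cyt"]])$value)
  }
  a <- run_at(1e-8, 1e-12)
  b <- run_at(5e-9, 5e-13)
  expect_lt(max(abs(a - b) / abs(a)), 0.005)
})
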