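# Reaction core: derivative assembly, conservation laws, integration.

test_that("mass-action derivatives follow the rate law", {
  net <- toy_ab_network(k = 2)
  d <- network_derivative(net, c(A = 1, B = 0))
  expect_equal(unname(d["A"]), -2)
  expect_equal(unname(d["B"]), 2)

  # reversible binding at its equilibrium has zero net derivative
  net2 <- toy_reversible_network(kon = 3, koff = 1.5)
  # equilibrium: kon * Glu * R = koff * GluR with Kd = 0.5
  # pick GluR = 0.5, Glu = R = 0.5 -> 3*0.25 = 1.5*0.5
  d2 <- network_derivative(net2, c(Glu = 0.5, R = 0.5, GluR = 0.5))
  expect_true(all(abs(d2) < 1e-12))
})

test_that("empty reaction list gives identically zero derivative", {
  net <- new_network()
  net <- add_species(net, c("X", "Y"), "cytosol", c(1, 2))
  d <- network_derivative(net, c(X = 1, Y = 2))
  expect_equal(unname(d), c(0, 0))
})

test_that("validation errors name the offending species and inputs", {
  net <- new_network()
  net <- add_species(net, "A", "cytosol", 1)
  expect_error(
    add_reaction(net, "bad", c(A = -1, X = 1), law = "mass_action",
                 params = c(k = 1)),
    "X")
  expect_error(add_reaction(net, "nolaw", c(A = -1), law = "mass_action",
                            params = numeric()), "k")
  expect_error(network_derivative(net, c(A = -1)), "negative")
})

test_that("derivative matches a brute-force per-reaction oracle", {
  model <- mglur_spine_model()
  net <- model$network
  base <- mglur_spine_baseline()
  inputs <- list(glu_mglur = function(t) 3, glu_psd = function(t) 3)
  set.seed(42)
  for (i in 1:20) {
    st <- base * exp(stats::runif(length(base), -0.5, 0.5))
    names(st) <- names(base)
    d1 <- network_derivative(net, st, t = 0.5, inputs = inputs)
    d2 <- oracle_derivative(net, st, t = 0.5, inputs = inputs)
    scale <- max(abs(d2), 1e-12)
    expect_lt(max(abs(d1 - d2[names(d1)])) / scale, 1e-9)
  }
})

test_that("conserved moieties span the left null space found by an oracle", {
  net <- toy_reversible_network()
  laws <- conserved_moieties(net)
  expect_length(laws, 2)  # receptor total and glutamate total

  S <- stoichiometry_matrix(net)
  oracle <- MASS::Null(S)          # left null space via t(t(S))
  expect_equal(ncol(oracle), 2)
  # every reported law is orthogonal to all reaction columns
  for (w in laws) expect_true(all(abs(crossprod(S, w)) < 1e-10))

  # a pure source breaks conservation for the produced species only
  net2 <- add_reaction(net, "src", c(Glu = 1), law = "custom",
                       params = list(src_k = 1), formula = "src_k")
  laws2 <- conserved_moieties(net2)
  expect_length(laws2, 1)
  expect_true(all(abs(vapply(laws2, function(w) w[["Glu"]], 0)) < 1e-10))
})

test_that("cross-compartment fluxes conserve amount, not concentration", {
  net <- new_network()
  net <- add_species(net, c("X_psd", "X_cyt"), c("PSD", "cytosol"), c(1, 0))
  net <- add_reaction(net, "move", c(X_psd = -1, X_cyt = 1),
                      law = "mass_action", params = c(k = 1), home = "PSD")
  d <- network_derivative(net, c(X_psd = 1, X_cyt = 0))
  # PSD (0.002) loses 1 uM/s; cytosol (0.02) gains only a tenth
  expect_equal(unname(d["X_psd"]), -1)
  expect_equal(unname(d["X_cyt"]), 0.1)

  out <- simulate_network(net, seq(0, 5, by = 0.1))
  amount <- 0.002 * out[, "X_psd"] + 0.02 * out[, "X_cyt"]
  expect_lt(diff(range(amount)) / amount[1], 1e-8)
})

test_that("conservation laws hold along a stimulated trajectory", {
  model <- mglur_spine_model()
  net <- model$network
  res <- spine_calibration_run()
  laws <- conserved_moieties(net)
  expect_gt(length(laws), 0)
  ser <- res$series[seq(1, nrow(res$series), by = 500), ]
  for (w in laws) {
    q <- apply(ser[, -1], 1, function(row)
      moiety_amount(net, w, stats::setNames(as.numeric(row),
                                            colnames(ser)[-1])))
    expect_lt(diff(range(q)) / max(abs(q[1]), 1e-9), 1e-6)
  }
})

test_that("simulated decay fixture matches its closed form", {
  fx <- make_fixture("exp_decay_network", rate = 1.3, A0 = 2)
  out <- simulate_network(fx$network, seq(0, 3, by = 0.05))
  expect_equal(out[, "A"], fx$analytic(out[, "time"]), tolerance = 1e-7)
})

test_that("solver reports are clipped to nonnegative concentrations", {
  net <- toy_ab_network(k = 50)
  out <- simulate_network(net, seq(0, 2, by = 0.01))
  expect_true(all(out[, -1] >= 0))
})
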