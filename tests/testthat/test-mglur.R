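# mGluRI cascade: conservation, basal behaviour, dose-response machinery.

test_that("receptor and G-alpha totals are conserved along a trajectory", {
  p <- mglur_params()
  net <- build_cascade_network(p)
  inp <- list(glu_mglur = function(t) ifelse(t < 5, 20, 0))
  out <- simulate_network(net, seq(0, 20, by = 0.05), inputs = inp,
                          restart_at = 5)
  cube <- grep("^m", net$species$name, value = TRUE)
  rec_tot <- rowSums(out[, cube])
  expect_lt(diff(range(rec_tot)) / p$R_tot, 1e-6)

  galpha <- c("Gq", "GaGTP", "GaGDP", "PLCa",
              grep("G$", cube, value = TRUE))
  ga_tot <- rowSums(out[, galpha])
  expect_lt(diff(range(ga_tot)) / p$G_tot, 1e-6)
})

test_that("without glutamate GalphaGTP holds its basal value", {
  net <- build_cascade_network()
  base <- spinesim:::cascade_baseline(net)
  expect_gt(base[["GaGTP"]], 0)          # constitutive cycling is nonzero
  out <- simulate_network(net, seq(0, 500, by = 10), init = base,
                          inputs = list(glu_mglur = function(t) 0))
  expect_lt(diff(range(out[, "GaGTP"])) / base[["GaGTP"]], 1e-4)
})

test_that("a glutamate step raises GalphaGTP to a higher plateau", {
  net <- build_cascade_network()
  base <- spinesim:::cascade_baseline(net)
  out <- simulate_network(net, seq(0, 2000, by = 10), init = base,
                          inputs = list(glu_mglur = function(t) 100))
  expect_gt(out[nrow(out), "GaGTP"], 5 * base[["GaGTP"]])
  # plateau: late derivative small relative to the excursion
  late <- out[out[, "time"] >= 1500, "GaGTP"]
  expect_lt(diff(range(late)), 0.05 * (max(out[, "GaGTP"]) - base[["GaGTP"]]))
})

test_that("disabling GTP hydrolysis makes GalphaGTP accumulate monotonically", {
  p <- mglur_params(k_hyd = 0, k_gap = 0, kp_on = 0, k_re = 0)
  net <- build_cascade_network(p)
  out <- simulate_network(net, seq(0, 300, by = 1),
                          inputs = list(glu_mglur = function(t) 100))
  g <- out[, "GaGTP"]
  expect_true(all(diff(g) > -1e-9))
  expect_gt(g[length(g)], g[2])
})

test_that("a synthetic single-site receptor recovers its Kd as EC50", {
  # one binding site, no activation/coupling asymmetry: collapse the cube by
  # neutralising all cooperativities; equilibrium occupancy must follow the
  # analytic isotherm c / (c + Kd)
  Kd <- 2
  # neutralise every cooperativity and switch off G coupling and exchange so
  # the cube collapses to one independent binding site per receptor
  p <- mglur_params(K_L = 1 / Kd, J = 1, beta = 1, kg_on = 0,
                    alpha_c = 1, gamma = 1, k_ex_act = 0, k_ex_basal = 0)
  db <- glutamate_binding_curve(10^seq(-2, 2, length.out = 12),
                                pulse_duration = 400, p = p,
                                gtp_free = FALSE,
                                net = build_cascade_network(p))
  expect_equal(attr(db, "fit")$ec50, Kd, tolerance = 0.02)
  iso <- db$dose / (db$dose + Kd)
  expect_equal(db$response, iso, tolerance = 1e-3)
})

test_that("cube equilibrium matches the analytic state weights", {
  p <- mglur_params(k_ex_act = 0, k_ex_basal = 0)
  net <- build_cascade_network(p)
  L <- 0.5
  out <- simulate_network(net, c(0, 2000, 4000),
                          inputs = list(glu_mglur = function(t) L),
                          rtol = 1e-10, atol = 1e-14)
  st <- out[nrow(out), ]
  wf <- spinesim:::cube_weight_factors(p)
  combos <- expand.grid(L = c(FALSE, TRUE), A = c(FALSE, TRUE),
                        G = c(FALSE, TRUE))
  g_free <- st[["Gq"]]
  w <- mapply(function(l, a, g) {
    wf(l, a, g) * (if (l) L else 1) * (if (g) g_free else 1)
  }, combos$L, combos$A, combos$G)
  names(w) <- mapply(spinesim:::cube_state_name, combos$L, combos$A,
                     combos$G)
  expected <- p$R_tot * w / sum(w)
  got <- vapply(names(w), function(nm) st[[nm]], 0)
  expect_equal(got, expected, tolerance = 1e-5)
})

test_that("IP3 balance restores basal and the 3-kinase is Ca-monotone", {
  p <- mglur_params()
  b <- ip3_balance(0, 0, 0.1, 0.06, p)
  expect_equal(b$net, 0, tolerance = 1e-12)
  # above basal IP3, net is negative; below, positive
  expect_lt(ip3_balance(0, 0, 0.2, 0.06, p)$net, 0)
  expect_gt(ip3_balance(0, 0, 0.05, 0.06, p)$net, 0)
  # 3-kinase degradation increases monotonically with calcium
  cas <- seq(0.05, 2, length.out = 20)
  d3k <- vapply(cas, function(ca) ip3_balance(0, 0, 0.5, ca, p)$degradation_3k, 0)
  expect_true(all(diff(d3k) > 0))
})

test_that("GalphaGTP dose-response is monotone and sorted internally", {
  dr <- cached("gtpgs_dr", {
    net <- build_cascade_network()
    galphagtp_dose_response(10^seq(-2, 3, length.out = 12), net = net)
  })
  expect_true(all(diff(dr$response) > -1e-6))
  expect_warning(galphagtp_dose_response(c(1, 0.1), duration = 1),
                 "sort")
})
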