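# Cleft glutamate: diffusion kernel, transporter uptake, summation.

test_that("single-release peaks at 1000 nm match the calibration anchors", {
  dp <- diffusion_params()
  peak_free <- glu_single_release_peak(1000, dp, tp = NULL)
  peak_up <- glu_single_release_peak(1000, dp, tp = transporter_params())
  expect_equal(peak_free, 40, tolerance = 0.01)
  expect_equal(peak_up, 32, tolerance = 0.01)
})

test_that("trace is ambient before the first release and superposes linearly", {
  dp <- diffusion_params(ambient = 0.05)
  ev <- release_events(c(0.1, 0.2))
  tr <- glutamate_timecourse(ev, 500, c(0, 0.05, 0.099), dp, tp = NULL)
  expect_equal(tr$glu, rep(0.05, 3))

  # two simultaneous events double the above-ambient trace
  t_grid <- seq(0, 0.4, by = 1e-3)
  one <- glutamate_timecourse(release_events(0), 500, t_grid, dp, NULL)
  two <- glutamate_timecourse(release_events(c(0, 0)), 500, t_grid, dp, NULL)
  expect_equal(two$glu - 0.05, 2 * (one$glu - 0.05), tolerance = 1e-10)
})

test_that("zero-density transporters reproduce the free-diffusion trace", {
  dp <- diffusion_params()
  t_grid <- seq(0, 0.5, by = 1e-3)
  free <- glutamate_timecourse(release_events(0), 800, t_grid, dp, NULL)
  zero <- glutamate_timecourse(release_events(0), 800, t_grid, dp,
                               transporter_params(density = 0))
  expect_equal(zero$glu, free$glu)
})

test_that("uptake flux obeys exclusion zone, zero-glutamate and monotonicity", {
  tp <- transporter_params()
  expect_equal(uptake_flux(0, 1000, tp), 0)
  expect_equal(uptake_flux(10, 150, tp), 0)    # inside 200 nm exclusion
  expect_gt(uptake_flux(10, 1000, tp), 0)

  # monotone and at most proportional in density
  dens <- seq(0, 1000, by = 100)
  flux <- vapply(dens, function(d)
    uptake_flux(10, 1000, transporter_params(density = d)), 0)
  expect_true(all(diff(flux) >= 0))
  expect_equal(flux[11], 2 * flux[6])
})

test_that("released mass is conserved without uptake", {
  pde <- solve_glu_pde(diffusion_params(), tp = NULL)
  mass <- rowSums(sweep(pde$C, 2, pde$vol, "*")) * MOLEC_PER_UM3_PER_UM
  expect_true(all(abs(mass - 3000) / 3000 < 0.01))
})

test_that("transporters never increase glutamate and PDE matches the kernel", {
  dp <- diffusion_params()
  t_grid <- c(1e-4, 1e-3, 5e-3, 0.02, 0.1, 0.5)
  for (r in c(300, 1000, 2000)) {
    with_tr <- glutamate_timecourse(release_events(0), r, t_grid, dp,
                                    transporter_params())$glu
    without <- glutamate_timecourse(release_events(0), r, t_grid, dp,
                                    NULL)$glu
    expect_true(all(with_tr <= without * 1.005 + 1e-6))
  }
  # PDE discretisation reproduces the closed-form free solution
  tiny <- transporter_params(k_bind = 1e-12)   # forces the PDE path
  pde_tr <- glutamate_timecourse(release_events(0), 1000,
                                 seq(0, 0.01, by = 1e-4),
                                 dp, tiny)$glu
  kern <- glutamate_timecourse(release_events(0), 1000,
                               seq(0, 0.01, by = 1e-4), dp, NULL)$glu
  expect_equal(max(pde_tr), max(kern), tolerance = 0.005)
})

test_that("pulse-train summation is limited by transporters, mostly far out", {
  dp <- diffusion_params()
  one <- summation_profile(100, 1, 1000, dp, transporter_params())
  tc <- glutamate_timecourse(release_events(0), 1000, one$time, dp,
                             transporter_params())
  expect_equal(one$glu, tc$glu)

  with_tr <- summation_profile(100, 4, 1000, dp, transporter_params())
  without <- summation_profile(100, 4, 1000, dp, NULL)
  expect_lt(max(with_tr$glu), max(without$glu))
  # accumulated level never exceeds the transporter-free level
  # the uptake trace comes from the PDE, the free trace from the closed
  # form; allow the sub-percent discretisation offset between the two paths
  expect_true(all(with_tr$glu <= without$glu * 1.005 + 1e-6))

  # near the release site the transporter effect collapses: relative peak
  # discrepancy at 100 nm at least 5x smaller than at 1000 nm
  rel <- function(r) {
    w <- max(summation_profile(100, 4, r, dp, transporter_params())$glu)
    f <- max(summation_profile(100, 4, r, dp, NULL)$glu)
    abs(f - w) / f
  }
  expect_gt(rel(1000) / max(rel(100), 1e-12), 5)
})

test_that("r = 0 is rejected with guidance", {
  expect_error(
    glutamate_timecourse(release_events(0), 0, c(0, 0.1)),
    "minimum|singular|> 0")
})
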