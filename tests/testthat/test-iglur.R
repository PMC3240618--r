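# AMPA/NMDA Markov schemes.

test_that("without glutamate the resting state is absorbing", {
  out <- iglur_response(function(t) 0, seq(0, 1, by = 0.01))
  expect_true(all(out$ampa_open == 0))
  expect_true(all(out$nmda_open == 0))
})

test_that("clamped glutamate relaxes to the stationary distribution", {
  p <- iglur_params()
  glu <- 100
  for (rec in c("ampa", "nmda")) {
    Q <- iglur_rate_matrix(glu, p, rec)
    ns <- MASS::Null(t(Q))             # stationary: Q pi = 0
    pi_stat <- ns[, 1] / sum(ns[, 1])
    names(pi_stat) <- rownames(Q)
    out <- iglur_response(function(t) glu, seq(0, 5, by = 0.05), p)
    open_nm <- paste0(rec, "_open")
    expect_equal(out[[open_nm]][nrow(out)],
                 unname(pi_stat[paste0(rec, "_O")]), tolerance = 1e-6)
  }
})

test_that("trajectory matches the matrix-exponential master equation", {
  p <- iglur_params()
  glu <- 50
  Q <- iglur_rate_matrix(glu, p, "nmda")
  p0 <- c(1, 0, 0, 0, 0)
  ts <- c(0.01, 0.05, 0.2, 1)
  out <- iglur_response(function(t) glu, c(0, ts), p)
  for (i in seq_along(ts)) {
    expected <- as.numeric(Matrix::expm(Q * ts[i]) %*% p0)
    names(expected) <- rownames(Q)
    expect_equal(out$nmda_open[i + 1], unname(expected["nmda_O"]),
                 tolerance = 1e-6)
  }
})

test_that("pulse then washout: open returns to rest, desensitised overshoots", {
  glu_fun <- function(t) ifelse(t >= 0 & t < 0.005, 1000, 0)
  net <- new_network()
  net <- add_species(net, "Ca_psd", "PSD", 0)
  net <- add_iglur(net)
  out <- simulate_network(net, seq(0, 2, by = 1e-3),
                          inputs = list(glu_psd = glu_fun),
                          restart_at = 0.005, atol = 1e-10)
  expect_gt(max(out[, "ampa_O"]), 0.05)
  expect_lt(out[nrow(out), "ampa_O"], 1e-4)
  expect_gt(max(out[, "ampa_D"]), 0.2)        # transient desensitisation
  expect_lt(out[nrow(out), "ampa_D"], 0.05)
  # occupancy normalisation conserved for both schemes
  for (pre in c("ampa_", "nmda_")) {
    tot <- rowSums(out[, paste0(pre, c("C0", "C1", "C2", "O", "D"))])
    expect_true(all(abs(tot - 1) < 1e-8))
  }
})

test_that("NMDA calcium flux is linear in open fraction and receptor count", {
  p <- iglur_params()
  expect_equal(nmda_calcium_flux(0, 20, p), 0)
  expect_equal(nmda_calcium_flux(0.4, 20, p), 2 * nmda_calcium_flux(0.2, 20, p))
  expect_equal(nmda_calcium_flux(0.4, 40, p), 2 * nmda_calcium_flux(0.4, 20, p))
})

test_that("fast AMPA responses are insensitive to glutamate transporters", {
  # the AMPA peak is set within the first millisecond, before uptake has
  # removed any appreciable glutamate; the slow NMDA scheme integrates the
  # late cleft tail and retains a transporter sensitivity of order 10% in
  # this geometry (see the methods vignette for the limitation)
  dp <- diffusion_params()
  r <- iglur_params()$receptor_radius
  ev <- release_events(0)
  t_grid <- seq(0, 0.3, by = 2e-4)
  for (setting in list(transporter_params(), NULL)) {
    tr <- glutamate_timecourse(ev, r, t_grid, dp, setting)
    f <- stats::approxfun(tr$time, tr$glu, rule = 2)
    res <- iglur_response(f, t_grid)
    nm <- if (is.null(setting)) "free" else "uptake"
    assign(nm, res)
  }
  rel_a <- abs(max(uptake$ampa_open) - max(free$ampa_open)) /
    max(free$ampa_open)
  expect_lt(rel_a, 0.01)
  rel_n <- abs(max(uptake$nmda_open) - max(free$nmda_open)) /
    max(free$nmda_open)
  expect_lt(rel_n, 0.2)
})
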