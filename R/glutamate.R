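# Glutamate release, radial diffusion and transporter uptake.
#
# A release event deposits ~3000 glutamate molecules as a point source at the
# centre of the synaptic cleft. The cleft plus perisynaptic space is treated
# as a thin disc of effective height h (a porous-sheet geometry): the
# free-diffusion solution is the 2-D Gaussian
#   C(r, t) = N / (4 pi D (t + t0) h) * exp(-r^2 / (4 D (t + t0)))
# where t0 = sigma0^2 / (4 D) encodes the finite initial spread of the
# released cloud. The effective height is calibrated so that a single release
# of 3000 molecules peaks at 40 uM at r = 1000 nm without uptake (the peak
# over time, N e^-1 / (pi r^2 h), is independent of D; D only sets timing).
#
# Generic transporters are distributed beyond an exclusion radius (200 nm)
# at 0.5 mM and act as a pseudo-first-order sink k_bind * density * (C - amb)
# (two-step binding/translocation collapsed to its rate-limiting binding step;
# at the <= 40 uM glutamate concentrations seen beyond the exclusion zone the
# 500 uM transporter pool is far from saturation, so the first-order form is
# exact to within a few percent). With uptake there is no closed form; the
# radial diffusion-uptake equation is solved once per parameter set on a
# log-spaced finite-volume grid and single-release traces are superposed
# (the sink is linear, so superposition is exact).

#' Diffusion parameters for the cleft glutamate field
#'
#' @param D effective (tortuosity-corrected) diffusion coefficient, um^2/s
#' @param h effective disc height, um; default calibrated so one release of
#'   3000 molecules peaks at 40 uM at 1000 nm without transporters
#' @param sigma0 initial Gaussian spread of the released cloud, um
#' @param ambient ambient glutamate concentration, uM
#' @return object of class \code{diffusion_params}
#' @export
diffusion_params <- function(D = 330, h = 0.0145834, sigma0 = 0.2,
                             ambient = 0) {
  stopifnot(D > 0, h > 0, sigma0 > 0, ambient >= 0)
  structure(list(D = D, h = h, sigma0 = sigma0, ambient = ambient),
            class = "diffusion_params")
}

#' Transporter parameters for glutamate uptake
#'
#' @param density transporter concentration beyond the exclusion radius, uM
#'   (default 500 uM = 0.5 mM)
#' @param exclusion_radius no-transporter zone around the release site, nm
#' @param k_bind binding rate constant, per uM per s; the pseudo-first-order
#'   uptake rate is \code{k_bind * density}. Default calibrated so the
#'   single-release peak at 1000 nm is 32 uM (vs 40 uM without uptake).
#' @return object of class \code{transporter_params}
#' @export
transporter_params <- function(density = 500, exclusion_radius = 200,
                               k_bind = 0.7601223) {
  stopifnot(density >= 0, exclusion_radius >= 0, k_bind >= 0)
  structure(list(density = density, exclusion_radius = exclusion_radius,
                 k_bind = k_bind), class = "transporter_params")
}

#' Release events of a stimulation protocol
#'
#' @param time event times in s, nondecreasing
#' @param molecules molecules per event (default 3000), recycled
#' @return data.frame with columns \code{time}, \code{molecules}
#' @export
release_events <- function(time, molecules = 3000) {
  stopifnot(all(molecules > 0), !is.unsorted(time))
  data.frame(time = time, molecules = rep_len(molecules, length(time)))
}

#' Closed-form free-diffusion kernel (no uptake)
#'
#' Concentration at radius r and time t after one release, uM above ambient.
#' Vectorised over \code{t}.
#'
#' @param r radius, nm
#' @param t time after release, s (values < 0 give 0)
#' @param dp \code{\link{diffusion_params}}
#' @param molecules released molecule count
#' @return concentration above ambient, uM
#' @export
glu_kernel <- function(r, t, dp = diffusion_params(), molecules = 3000) {
  r_um <- r / 1000
  t0 <- dp$sigma0^2 / (4 * dp$D)
  tt <- t + t0
  out <- ifelse(t < 0, 0,
    molecules / (4 * pi * dp$D * tt * dp$h * MOLEC_PER_UM3_PER_UM) *
      exp(-r_um^2 / (4 * dp$D * tt)))
  out
}

#' Glutamate uptake flux
#'
#' Pseudo-first-order transporter sink. Zero inside the exclusion radius and
#' zero at ambient glutamate; linear (hence monotone) in transporter density.
#'
#' @param glu local glutamate concentration, uM
#' @param r radius from the release site, nm
#' @param tp \code{\link{transporter_params}}
#' @param ambient ambient glutamate concentration, uM
#' @return removal flux, uM/s (>= 0)
#' @export
uptake_flux <- function(glu, r, tp = transporter_params(), ambient = 0) {
  stopifnot(all(glu >= 0))
  k <- ifelse(r < tp$exclusion_radius, 0, tp$k_bind * tp$density)
  pmax(k * (glu - ambient), 0)
}

# Finite-volume radial grid (log-spaced) for the diffusion-uptake PDE.
radial_grid <- function(r_min = 0.01, r_max = 60, n = 260) {
  r <- exp(seq(log(r_min), log(r_max), length.out = n))
  faces <- c(r[1] * sqrt(r[1] / r[2]), sqrt(r[-n] * r[-1]),
             r[n] * sqrt(r[n] / r[n - 1]))
  list(r = r, faces = faces, n = n)
}

# Solve the single-release radial diffusion(-uptake) problem.
# Returns list(t = times, r = radii um, C = matrix time x radius, uM).
solve_glu_pde <- function(dp, tp = NULL, molecules = 3000, t_end = 10,
                          n_r = 260, n_t = 220) {
  g <- radial_grid(n = n_r)
  r <- g$r; faces <- g$faces; n <- g$n
  area <- pi * (faces[-1]^2 - faces[-(n + 1)]^2)      # annulus area, um^2
  vol <- area * dp$h                                   # cell volume, um^3
  # face conductance: D * (2 pi r_face h) / dr, amount/s per (molec/um^3)
  inner <- faces[2:n]
  cond <- dp$D * 2 * pi * inner * dp$h / (r[-1] - r[-n])
  k_up <- if (is.null(tp)) numeric(n) else
    ifelse(r * 1000 >= tp$exclusion_radius, tp$k_bind * tp$density, 0)

  # initial condition: Gaussian cloud, molecules/um^3
  t0 <- dp$sigma0^2 / (4 * dp$D)
  C0 <- molecules / (4 * pi * dp$D * t0 * dp$h) * exp(-r^2 / (4 * dp$D * t0))
  # renormalise to the exact molecule count on the discrete grid
  C0 <- C0 * molecules / sum(C0 * vol)

  rhs <- function(t, C, p) {
    flux <- cond * (C[-1] - C[-n])      # molecules/s across interior faces
    dC <- (c(flux, 0) - c(0, flux)) / vol - k_up * C
    list(dC)
  }
  times <- c(0, exp(seq(log(1e-6), log(t_end), length.out = n_t - 1)))
  sol <- deSolve::ode(y = C0, times = times, func = rhs, parms = NULL,
                      method = "lsode", jactype = "bandint", bandup = 1,
                      banddown = 1, rtol = 1e-8, atol = 1e-6)
  list(t = times, r = r, C = sol[, -1, drop = FALSE] / MOLEC_PER_UM3_PER_UM,
       vol = vol)
}

# Cache of single-release PDE solutions keyed by parameter signature.
.glu_cache <- new.env(parent = emptyenv())

glu_pde_cached <- function(dp, tp) {
  key <- paste(c(unlist(dp), if (is.null(tp)) "off" else unlist(tp)),
               collapse = "|")
  if (is.null(.glu_cache[[key]]))
    .glu_cache[[key]] <- solve_glu_pde(dp, tp)
  .glu_cache[[key]]
}

# Single-release trace at radius r (nm): returns function(t) uM above ambient,
# per 3000 molecules.
single_release_trace <- function(r, dp, tp = NULL) {
  if (r <= 0) stop("r must be > 0 nm: the point source is singular at r = 0; ",
                   "evaluate at the receptor's finite radius")
  if (is.null(tp) || tp$density == 0 || tp$k_bind == 0) {
    function(t) glu_kernel(r, t, dp)
  } else {
    pde <- glu_pde_cached(dp, tp)
    r_um <- r / 1000
    lr <- log(pde$r)
    i <- findInterval(log(r_um), lr, all.inside = TRUE)
    wgt <- (log(r_um) - lr[i]) / (lr[i + 1] - lr[i])
    prof <- (1 - wgt) * pde$C[, i] + wgt * pde$C[, i + 1]
    f <- stats::approxfun(pde$t, prof, yleft = 0, yright = 0)
    function(t) {
      out <- numeric(length(t))
      ok <- t >= 0
      out[ok] <- f(pmin(t[ok], max(pde$t)))
      out
    }
  }
}

#' Glutamate concentration time course at a radius
#'
#' Superposes single-release solutions for every event in the protocol (the
#' diffusion-uptake system is linear, so superposition is exact) on top of the
#' ambient concentration.
#'
#' @param events \code{\link{release_events}} data.frame
#' @param r radius from the release site, nm (> 0)
#' @param times output times, s
#' @param dp \code{\link{diffusion_params}}
#' @param tp \code{\link{transporter_params}} or \code{NULL} for no uptake
#' @return data.frame with columns \code{time} (s) and \code{glu} (uM)
#' @export
glutamate_timecourse <- function(events, r, times,
                                 dp = diffusion_params(),
                                 tp = transporter_params()) {
  stopifnot(is.data.frame(events), !is.unsorted(events$time))
  base <- single_release_trace(r, dp, tp)
  glu <- rep(dp$ambient, length(times))
  for (e in seq_len(nrow(events)))
    glu <- glu + base(times - events$time[e]) * events$molecules[e] / 3000
  data.frame(time = times, glu = glu)
}

#' Glutamate field evaluator
#'
#' @inheritParams glutamate_timecourse
#' @return function(r_nm, t_s) returning glutamate concentration in uM
#' @export
glutamate_field <- function(events, dp = diffusion_params(),
                            tp = transporter_params()) {
  force(events); force(dp); force(tp)
  function(r, t) glutamate_timecourse(events, r, t, dp, tp)$glu
}

#' Pulse-train glutamate accumulation profile
#'
#' @param frequency pulse frequency, Hz (> 0)
#' @param n_pulses number of pulses
#' @param r radius, nm
#' @param times output times, s; default covers the train plus 0.5 s
#' @inheritParams glutamate_timecourse
#' @return data.frame with columns \code{time}, \code{glu}
#' @export
summation_profile <- function(frequency, n_pulses, r,
                              dp = diffusion_params(),
                              tp = transporter_params(),
                              times = NULL) {
  stopifnot(frequency > 0, n_pulses >= 1)
  ev <- release_events(seq(0, by = 1 / frequency, length.out = n_pulses))
  if (is.null(times)) {
    span <- (n_pulses - 1) / frequency + 0.5
    times <- seq(0, span, by = 1e-4)
  }
  glutamate_timecourse(ev, r, times, dp, tp)
}

#' Peak glutamate concentration after a single release
#'
#' Convenience used by calibration and tests: maximum of the single-release
#' trace at radius \code{r}.
#'
#' @param r radius, nm
#' @inheritParams glutamate_timecourse
#' @return peak concentration, uM
#' @export
glu_single_release_peak <- function(r, dp = diffusion_params(),
                                    tp = transporter_params()) {
  base <- single_release_trace(r, dp, tp)
  tt <- c(0, exp(seq(log(1e-6), log(5), length.out = 600)))
  max(base(tt)) + dp$ambient
}
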