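# Assembly of the full spine model from a parameter configuration, baseline
# equilibration, and derived-at-assembly constants.
#
# Three constants are solved at assembly time so that the stated resting
# concentrations are an exact fixed point of the assembled system, mirroring
# the usual "leak balances pump at rest" construction:
#   * the plasma-membrane leak balances PMCA + NCX at basal cytosolic Ca;
#   * the ER leak balances SERCA minus the basal IP3R flux at basal ER Ca;
#   * the PIP2 hydrolysis constant k_pip2 makes basal IP3 production by the
#     constitutively active PLC pool equal basal IP3 degradation, pinning
#     resting IP3 (the resting IP3 level is maintained by constitutive PLC
#     activity, not by an explicit source term).

#' Default model configuration
#'
#' Collects the parameter blocks of every module plus the simulation settings
#' (mGluRI location, transporter switch, receptor subset, solver tolerances,
#' output grid).
#'
#' @param ... named overrides applied with \code{modifyList} semantics at the
#'   top level (supply whole sub-lists to override nested values)
#' @return nested configuration list of class \code{spine_config}
#' @export
spine_config <- function(...) {
  cfg <- list(
    compartments = list(cleft = 0.0015, PSD = 0.002, cytosol = 0.02,
                        ER = 0.002),
    diffusion = unclass(diffusion_params()),
    transporters = unclass(transporter_params()),
    mglur = mglur_params(),
    ip3r = ip3r_params(),
    calcium = calcium_params(),
    iglur = iglur_params(),
    simulation = list(
      mglur_location = 100,     # nm from the release site
      transporters = "on",
      receptors = "all",        # "all", "mglur", "iglur"
      dt = 0.001,               # output grid, s
      post_stimulus = 20,       # recorded tail after the last release, s
      rtol = 1e-8, atol = 1e-12,
      ip3_basal = 0.1
    )
  )
  out <- utils::modifyList(cfg, list(...))
  class(out) <- c("spine_config", "list")
  out
}

validate_config <- function(cfg) {
  need <- c("compartments", "diffusion", "transporters", "mglur", "ip3r",
            "calcium", "iglur", "simulation")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("configuration is missing block(s): ", paste(miss, collapse = ", "))
  vols <- unlist(cfg$compartments)
  if (any(vols <= 0))
    stop("compartments: volume must be > 0 (offending: ",
         paste(names(vols)[vols <= 0], collapse = ", "), ")")
  if (!setequal(names(vols), c("cleft", "PSD", "cytosol", "ER")))
    stop("compartments: exactly cleft, PSD, cytosol, ER are required")
  if (cfg$simulation$mglur_location <= 0)
    stop("simulation$mglur_location must be > 0 nm")
  if (!cfg$simulation$receptors %in% c("all", "mglur", "iglur"))
    stop("simulation$receptors must be one of all, mglur, iglur")
  if (!cfg$simulation$transporters %in% c("on", "off"))
    stop("simulation$transporters must be 'on' or 'off'")
  with(cfg$diffusion, stopifnot(D > 0, h > 0, sigma0 > 0, ambient >= 0))
  with(cfg$transporters,
       stopifnot(density >= 0, exclusion_radius >= 0, k_bind >= 0))
  invisible(cfg)
}

#' Assemble the full spine reaction network
#'
#' Builds the compartmentalised network from a configuration: calcium
#' homeostasis (pumps, buffers, PSD/cytosol exchange), the mGluRI cascade
#' (with the constitutive IP3 production derived to pin basal IP3 unless
#' finite value with \code{derive_basal = FALSE} in the mglur block), the
#' IP3R/ER module and, depending on the receptor subset, the AMPA/NMDA
#' schemes.
#'
#' @param cfg a \code{\link{spine_config}}
#' @return object of class \code{spine_model}: list with \code{network},
#'   \code{config}, and the resolved cascade basal state
#' @export
assemble_spine_model <- function(cfg = spine_config()) {
  validate_config(cfg)
  sim <- cfg$simulation
  pm <- do.call(mglur_params, cfg$mglur[names(cfg$mglur) != "derive_basal"])
  pc <- do.call(calcium_params, cfg$calcium)
  pr <- do.call(ip3r_params, cfg$ip3r)
  pig <- do.call(iglur_params, cfg$iglur)

  derive <- if (!is.null(cfg$mglur$derive_basal)) cfg$mglur$derive_basal
            else TRUE
  with_mglur <- sim$receptors %in% c("all", "mglur")
  with_iglur <- sim$receptors %in% c("all", "iglur")

  cascade_basal <- NULL
  if (with_mglur && derive) {
    # derive the constitutive IP3 production so that resting IP3 is a fixed
    # point: total production (constitutive + basal receptor-driven PLC*)
    # equals degradation at (ip3_basal, ca_basal)
    cascade_basal <- cascade_baseline(build_cascade_network(pm, pc$ca_basal))
    plca_b <- as.numeric(cascade_basal["PLCa"])
    deg <- ip3_balance(0, 0, sim$ip3_basal, pc$ca_basal, pm)
    phi <- deg$degradation_3k + deg$degradation_5p
    pip2_b <- pm$PIP2_tot - phi / pm$k_rep
    pm$v_ip3_basal <- max(phi - pm$k_pip2 * plca_b * pip2_b, 0)
    if (pm$v_ip3_basal == 0)
      warning("basal receptor-driven IP3 production alone exceeds basal ",
              "degradation; resting IP3 will sit above the configured basal")
  }

  comp <- data.frame(name = names(cfg$compartments),
                     volume = unlist(cfg$compartments),
                     stringsAsFactors = FALSE)
  net <- new_network(comp)
  net <- add_species(net, "IP3_cyt", "cytosol", sim$ip3_basal)
  net <- add_calcium_homeostasis(net, pc)
  if (with_mglur) {
    net <- add_mglur_cascade(net, pm)
    if (!is.null(cascade_basal)) {
      # start the cascade at its basal equilibrium (PIP2 at its own balance)
      nm <- intersect(names(cascade_basal), net$species$name)
      nm <- setdiff(nm, c("Ca_cyt", "IP3_cyt"))
      net$species$initial[match(nm, net$species$name)] <-
        as.numeric(cascade_basal[nm])
      phi <- ip3_balance(0, 0, sim$ip3_basal, pc$ca_basal, pm)
      net$species$initial[net$species$name == "PIP2"] <-
        pm$PIP2_tot - (phi$degradation_3k + phi$degradation_5p) / pm$k_rep
    }
  } else {
    # IP3 still needs its degradation path (Ca-dependent 3-kinase acts on
    # NMDA-driven calcium even without mGluRI) plus a constant basal source
    deg <- ip3_balance(0, 0, sim$ip3_basal, pc$ca_basal, pm)
    phi <- deg$degradation_3k + deg$degradation_5p
    hill_b <- pc$ca_basal^pm$n_plc_ca /
      (pm$K_plc_ca^pm$n_plc_ca + pc$ca_basal^pm$n_plc_ca)
    net <- add_reaction(net, "ip3_basal_source",
      c(IP3_cyt = 1), law = "custom",
      params = list(ip3_src = phi, hill_plc_basal = hill_b,
                    K_plc_ca = pm$K_plc_ca, n_plc_ca = pm$n_plc_ca),
      formula = paste0(
        "ip3_src / hill_plc_basal * Ca_cyt^n_plc_ca / (",
        "K_plc_ca^n_plc_ca + Ca_cyt^n_plc_ca)"),
      modifiers = "Ca_cyt", home = "cytosol")
    net <- add_reaction(net, "ip3_3kinase",
      c(IP3_cyt = -1), law = "custom",
      params = list(V3k = pm$V3k, K3k_ca = pm$K3k_ca, n3k = pm$n3k,
                    Km3k = pm$Km3k),
      formula = paste0("V3k * Ca_cyt^n3k / (K3k_ca^n3k + Ca_cyt^n3k)",
                       " * IP3_cyt / (Km3k + IP3_cyt)"),
      modifiers = "Ca_cyt", home = "cytosol")
    net <- add_reaction(net, "ip3_5phosphatase",
      c(IP3_cyt = -1), law = "custom",
      params = list(V5p = pm$V5p, Km5p = pm$Km5p),
      formula = "V5p * IP3_cyt / (Km5p + IP3_cyt)", home = "cytosol")
  }
  net <- add_ip3r_er(net, pr, ca_basal = pc$ca_basal,
                     ip3_basal = sim$ip3_basal)
  if (with_iglur) net <- add_iglur(net, pig)

  structure(list(network = compile_network(net), config = cfg,
                 params = list(mglur = pm, calcium = pc, ip3r = pr,
                               iglur = pig),
                 cascade_basal = cascade_basal),
            class = "spine_model")
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model>\n")
  print(x$network)
  sim <- x$config$simulation
  cat("  receptors:", sim$receptors, "| mGluRI at", sim$mglur_location,
      "nm | transporters", sim$transporters, "\n")
  invisible(x)
}

#' Equilibrate a spine model to its resting state
#'
#' Integrates the assembled system without any glutamate release until the
#' largest relative time-derivative falls below \code{tol}, and returns the
#' baseline state. Reports the resting cytosolic Ca, IP3, cleft and ER Ca as
#' attributes.
#'
#' @param model a \code{spine_model}
#' @param t_max maximum simulated equilibration time, s
#' @param tol convergence tolerance on max |dc/dt| / max(c, 1e-3), 1/s
#' @return named baseline state vector with attribute \code{baselines}
#' @export
equilibrate <- function(model, t_max = 50000, tol = 1e-9) {
  net <- model$network
  zero <- list(glu_mglur = function(t) 0, glu_psd = function(t) 0)
  st <- initial_state(net)
  total <- 0
  chunk <- 5000
  repeat {
    out <- simulate_network(net, times = c(0, chunk / 2, chunk), init = st,
                            inputs = zero, rtol = 1e-10, atol = 1e-14)
    st <- out[nrow(out), -1]
    total <- total + chunk
    d <- network_derivative(net, st, t = 0, inputs = zero)
    resid <- max(abs(d) / pmax(abs(st), 1e-3))
    if (resid < tol) break
    if (total >= t_max)
      stop("equilibration did not converge within ", t_max,
           " s: max residual ", signif(resid, 3), " 1/s")
  }
  base <- stats::setNames(as.numeric(st), names(st))
  attr(base, "baselines") <- c(
    Ca_cyt = as.numeric(st["Ca_cyt"]),
    IP3_cyt = as.numeric(st["IP3_cyt"]),
    Ca_cleft = as.numeric(st["Ca_cleft"]),
    Ca_ER = as.numeric(st["Ca_ER"]))
  attr(base, "residual") <- max(abs(network_derivative(net, st, 0, zero)) /
                                  pmax(abs(st), 1e-3))
  base
}

# internal: cached equilibration per model signature
.baseline_cache <- new.env(parent = emptyenv())

model_baseline <- function(model) {
  key <- paste(format(unlist(model$config), digits = 12), collapse = "|")
  hit <- .baseline_cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- equilibrate(model)
  .baseline_cache[[key]] <- base
  base
}

#' Run a stimulation protocol on a spine model
#'
#' Computes the glutamate concentration transients at the mGluRI location and
#' at the AMPA/NMDA cluster (20 nm) for the protocol's release events using
#' the cleft diffusion(-uptake) model, then integrates the full network from
#' its equilibrated baseline with those forcings.
#'
#' @param model a \code{spine_model}
#' @param protocol a \code{\link{make_protocol}} object (or a
#'   \code{release_events} data.frame)
#' @param duration total simulated time, s; default protocol span +
#'   \code{post_stimulus} from the configuration
#' @param baseline optional precomputed baseline state
#' @param glu_override optional function(t) -> uM applied identically at
#'   every receptor location instead of the diffusion model (used for square
#'   bath applications)
#' @return object of class \code{spine_result}: list with \code{series}
#'   (data.frame), \code{baseline}, \code{config}, \code{protocol}
#' @export
run_protocol <- function(model, protocol, duration = NULL, baseline = NULL,
                         glu_override = NULL, extra_restarts = numeric(0)) {
  sim <- model$config$simulation
  events <- if (inherits(protocol, "stimulus_protocol")) protocol$events
            else protocol
  if (is.null(baseline)) baseline <- model_baseline(model)
  span <- if (nrow(events)) max(events$time) else 0
  if (is.null(duration)) duration <- span + sim$post_stimulus
  if (nrow(events) && duration <= span)
    stop("duration must exceed the protocol span (", span, " s)")

  dp <- do.call(diffusion_params, model$config$diffusion)
  tp <- if (sim$transporters == "on")
    do.call(transporter_params, model$config$transporters) else NULL

  times <- seq(0, duration, by = sim$dt)
  inputs <- list()
  if (!is.null(glu_override)) {
    inputs$glu_mglur <- glu_override
    inputs$glu_psd <- glu_override
  } else if (nrow(events)) {
    inputs$glu_mglur <- glu_forcing(events, sim$mglur_location, dp, tp,
                                    duration)
    inputs$glu_psd <- glu_forcing(events,
                                  model$params$iglur$receptor_radius, dp, tp,
                                  duration)
  } else {
    inputs$glu_mglur <- function(t) dp$ambient
    inputs$glu_psd <- function(t) dp$ambient
  }

  out <- simulate_network(model$network, times, init = baseline,
                          inputs = inputs,
                          restart_at = c(events$time, extra_restarts),
                          rtol = sim$rtol, atol = sim$atol)
  ser <- as.data.frame(out)
  ser$glu_mglur <- inputs$glu_mglur(ser$time)
  ser$glu_psd <- inputs$glu_psd(ser$time)
  structure(list(series = ser, baseline = baseline, config = model$config,
                 protocol = events),
            class = "spine_result")
}

# Precompute a fast piecewise-linear forcing for a protocol at one radius.
glu_forcing <- function(events, r, dp, tp, duration) {
  base <- single_release_trace(r, dp, tp)
  # dense grid after each event, coarse elsewhere
  local_t <- c(seq(0, 0.005, by = 5e-5), exp(seq(log(0.005), log(2), length.out = 160)))
  grid <- sort(unique(c(0, duration,
                        as.vector(outer(local_t, events$time, `+`)),
                        seq(0, duration, by = 0.01))))
  grid <- grid[grid <= duration]
  val <- rep(dp$ambient, length(grid))
  for (e in seq_len(nrow(events)))
    val <- val + base(grid - events$time[e]) * events$molecules[e] / 3000
  f <- stats::approxfun(grid, val, rule = 2)
  f
}

#' @export
print.spine_result <- function(x, ...) {
  s <- x$series
  cat("<spine_result> ", nrow(s), " samples over ", max(s$time), " s\n",
      sep = "")
  for (v in intersect(c("Ca_cyt", "IP3_cyt"), names(s)))
    cat("  peak ", v, ": ", signif(max(s[[v]]), 4), " uM\n", sep = "")
  invisible(x)
}
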