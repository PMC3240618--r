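# Group-I metabotropic glutamate receptor cascade.
#
# Receptor activation follows a cubic ternary-complex scheme: eight receptor
# states spanning {ligand-free/bound} x {inactive/active} x {G-free/coupled},
# with thermodynamically consistent edge constants derived from multiplicative
# state weights (ligand affinity K_L, activation constant J, G-coupling
# affinity M, and cooperativity factors beta, gamma, alpha_c, delta). Agonist-
# and activity-dependent nucleotide exchange ejects GalphaGTP + Gbetagamma
# from coupled active states, driving a G-protein cycle (intrinsic GTPase,
# PLC-accelerated GTPase, and heterotrimer reassociation). GalphaGTP binds
# PLC in a Ca-dependent manner; active PLC hydrolyses PIP2 into IP3 + DAG;
# IP3 is degraded by a Ca-dependent 3-kinase (to IP4) and a 5-phosphatase
# (to IP2).
#
# Two features of the scheme matter for its dose-response behaviour. Receptors
# pre-coupled to G bind glutamate with ~10-fold higher affinity, so a brief
# (10 s) application titrates the high-affinity coupled pool. Under sustained
# stimulation the exchange step strips G from the receptor much faster than
# the slow heterotrimer re-association restores it, so the steady-state
# GalphaGTP production tracks occupancy of the *uncoupled* (low-affinity)
# receptor, yielding a functional EC50 roughly tenfold higher than the
# binding EC50.

#' Default mGluRI cascade parameters
#'
#' All first-order rates in 1/s, second-order in 1/(uM s), concentrations uM.
#' Edge rate constants of the receptor cube are derived from the state-weight
#' factors so every closed loop satisfies microscopic reversibility.
#'
#' @param ... named overrides of any default
#' @return list of parameters
#' @export
mglur_params <- function(...) {
  p <- list(
    R_tot = 8,          # total receptor (five receptors in the perisynaptic shell)
    G_tot = 40,         # total Gq alpha (and betagamma) pool
    PLC_tot = 0.5,      # small pool; saturates during strong transients
    PIP2_tot = 40,
    # cube thermodynamics; ligand affinity and the ligand-G cooperativity are
    # the two calibration anchors (functional EC50 5.6 uM under GTP turnover,
    # high-affinity binding EC50 0.56 uM in the nucleotide-free condition)
    K_L = 0.105,        # ligand association constant to bare R, 1/uM
    J = 0.02,           # constitutive activation equilibrium R* / R
    beta = 20,          # ligand-activation cooperativity
    M = 1e-4,           # G association constant to bare R, 1/uM
    gamma = 1,          # activation-G cooperativity
    alpha_c = 3450,     # ligand-G cooperativity (high-affinity coupled state)
    delta = 1,          # triple cooperativity
    # cube kinetics
    kon_L = 4,          # ligand on-rate, all states
    kact = 50,          # activation flip forward rate, all states
    kg_on = 0.04,       # G association on-rate
    # nucleotide exchange and G cycle
    k_ex_act = 50,      # exchange from LR*G (agonist-bound active coupled)
    k_ex_basal = 0.05,  # exchange from R*G (constitutive)
    k_hyd = 5,          # intrinsic GTPase of free GalphaGTP (dominant
                        # removal; keeps the steady-state response linear)
    k_re = 0.5,         # GalphaGDP + Gbg reassociation
    # PLC branch
    kp_on = 20,         # GalphaGTP + PLC association (x Ca hill factor)
    kp_off = 0.2,
    k_gap = 2,          # GAP: PLC* -> PLC + GalphaGDP (accelerated GTPase)
    K_plc_ca = 0.3,     # Ca half-activation of PLC association
    n_plc_ca = 1,
    k_pip2 = 0.25,     # PLC* + PIP2 -> IP3 + DAG (per uM PLC* per s)
    v_ip3_basal = NA,   # constitutive (receptor-independent) PLC background
                        # IP3 production, uM/s; NA -> derived at assembly so
                        # that resting IP3 balances its degradation
    k_rep = 1,          # PIP2 replenishment toward PIP2_tot
    # IP3 degradation
    V3k = 120, K3k_ca = 0.4, n3k = 2, Km3k = 10,   # Ca-dependent IP3 3-kinase
    V5p = 14, Km5p = 10                            # IP3 5-phosphatase
  )
  utils::modifyList(p, list(...))
}

# State weight of a cube vertex (excluding explicit [L], [G] factors).
cube_weight_factors <- function(p) {
  function(L, A, G) {
    w <- 1
    if (L) w <- w * p$K_L
    if (A) w <- w * p$J
    if (G) w <- w * p$M
    if (L && A) w <- w * p$beta
    if (A && G) w <- w * p$gamma
    if (L && G) w <- w * p$alpha_c
    if (L && A && G) w <- w * p$delta
    w
  }
}

cube_state_name <- function(L, A, G) {
  paste0("m", if (L) "L" else "", "R", if (A) "a" else "", if (G) "G" else "")
}

#' Add the mGluRI cascade to a network
#'
#' Declares the eight receptor-cube states, the G-protein pools, the PLC
#' branch and the IP3 production/degradation reactions. Glutamate enters as a
#' time-varying model input named \code{glu_input} (uM at the receptor
#' location); calcium dependence reads the species named \code{ca_species}.
#'
#' @param net a \code{spine_network} that already declares \code{ca_species}
#'   and the IP3/DAG species compartmentalised in \code{compartment}
#' @param p parameter list from \code{\link{mglur_params}}
#' @param glu_input name of the glutamate forcing input
#' @param compartment compartment hosting the cascade species
#' @param ca_species calcium species regulating PLC and the 3-kinase
#' @return the updated network
#' @export
add_mglur_cascade <- function(net, p = mglur_params(),
                              glu_input = "glu_mglur",
                              compartment = "cytosol",
                              ca_species = "Ca_cyt") {
  wf <- cube_weight_factors(p)
  combos <- expand.grid(L = c(FALSE, TRUE), A = c(FALSE, TRUE),
                        G = c(FALSE, TRUE))
  states <- mapply(cube_state_name, combos$L, combos$A, combos$G)

  init <- stats::setNames(rep(0, length(states)), states)
  init["mR"] <- p$R_tot
  net <- add_species(net, states, compartment, init)
  net <- add_species(net, c("Gq", "GaGTP", "GaGDP", "Gbg"), compartment,
                     c(p$G_tot, 0, 0, 0))
  net <- add_species(net, c("PLC", "PLCa"), compartment, c(p$PLC_tot, 0))
  net <- add_species(net, c("PIP2", "DAG", "IP2", "IP4"), compartment,
                     c(p$PIP2_tot, 0, 0, 0))

  # --- receptor cube edges -------------------------------------------------
  for (i in seq_len(nrow(combos))) {
    L <- combos$L[i]; A <- combos$A[i]; G <- combos$G[i]
    from <- cube_state_name(L, A, G)
    # ligand binding edge (L: 0 -> 1)
    if (!L) {
      to <- cube_state_name(TRUE, A, G)
      Ka <- wf(TRUE, A, G) / wf(FALSE, A, G)     # 1/uM
      koff <- p$kon_L / Ka
      net <- add_reaction(net,
        paste0("bindL_", from),
        stats::setNames(c(-1, 1), c(from, to)), law = "custom",
        params = list(kon_mglur = p$kon_L),
        formula = paste0("kon_mglur * ", glu_input, " * ", from),
        modifiers = glu_input, home = compartment)
      net <- add_reaction(net,
        paste0("unbindL_", to),
        stats::setNames(c(-1, 1), c(to, from)), law = "mass_action",
        params = c(k = koff), home = compartment)
    }
    # activation edge (A: 0 -> 1)
    if (!A) {
      to <- cube_state_name(L, TRUE, G)
      Keq <- wf(L, TRUE, G) / wf(L, FALSE, G)
      net <- add_reaction(net,
        paste0("act_", from),
        stats::setNames(c(-1, 1), c(from, to)), law = "mass_action",
        params = c(k = p$kact), home = compartment)
      net <- add_reaction(net,
        paste0("deact_", to),
        stats::setNames(c(-1, 1), c(to, from)), law = "mass_action",
        params = c(k = p$kact / Keq), home = compartment)
    }
    # G-coupling edge (G: 0 -> 1)
    if (!G) {
      to <- cube_state_name(L, A, TRUE)
      KaG <- wf(L, A, TRUE) / wf(L, A, FALSE)    # 1/uM
      net <- add_reaction(net,
        paste0("gbind_", from),
        stats::setNames(c(-1, -1, 1), c(from, "Gq", to)),
        law = "mass_action", params = c(k = p$kg_on), home = compartment)
      net <- add_reaction(net,
        paste0("gunbind_", to),
        stats::setNames(c(-1, 1, 1), c(to, from, "Gq")),
        law = "mass_action", params = c(k = p$kg_on / KaG),
        home = compartment)
    }
  }

  # --- nucleotide exchange: coupled active states emit GaGTP + Gbg ---------
  net <- add_reaction(net, "exchange_LRaG",
    c(mLRaG = -1, mLRa = 1, GaGTP = 1, Gbg = 1),
    law = "mass_action", params = c(k = p$k_ex_act), home = compartment)
  net <- add_reaction(net, "exchange_RaG",
    c(mRaG = -1, mRa = 1, GaGTP = 1, Gbg = 1),
    law = "mass_action", params = c(k = p$k_ex_basal), home = compartment)

  # --- G cycle -------------------------------------------------------------
  net <- add_reaction(net, "gtpase_intrinsic",
    c(GaGTP = -1, GaGDP = 1), law = "mass_action",
    params = c(k = p$k_hyd), home = compartment)
  net <- add_reaction(net, "g_reassoc",
    c(GaGDP = -1, Gbg = -1, Gq = 1), law = "mass_action",
    params = c(k = p$k_re), home = compartment)

  # --- PLC branch ----------------------------------------------------------
  # Ca-dependent association of GaGTP with PLC ("in a Ca-dependent manner")
  net <- add_reaction(net, "plc_activate",
    c(GaGTP = -1, PLC = -1, PLCa = 1), law = "custom",
    params = list(kp_on_mglur = p$kp_on, K_plc_ca = p$K_plc_ca,
                  n_plc_ca = p$n_plc_ca),
    formula = paste0(
      "kp_on_mglur * GaGTP * PLC * ", ca_species, "^n_plc_ca / (",
      "K_plc_ca^n_plc_ca + ", ca_species, "^n_plc_ca)"),
    modifiers = ca_species, home = compartment)
  net <- add_reaction(net, "plc_deactivate",
    c(PLCa = -1, GaGTP = 1, PLC = 1), law = "mass_action",
    params = c(k = p$kp_off), home = compartment)
  # GAP: PLC-bound GalphaGTP hydrolyses quickly, releasing GaGDP
  net <- add_reaction(net, "plc_gap",
    c(PLCa = -1, PLC = 1, GaGDP = 1), law = "mass_action",
    params = c(k = p$k_gap), home = compartment)

  # --- PIP2 hydrolysis and replenishment ----------------------------------
  net <- add_reaction(net, "pip2_hydrolysis",
    c(PIP2 = -1, IP3_cyt = 1, DAG = 1), law = "custom",
    params = list(k_pip2 = p$k_pip2),
    formula = "k_pip2 * PLCa * PIP2",
    modifiers = "PLCa", home = compartment)
  net <- add_reaction(net, "pip2_replenish",
    c(PIP2 = 1), law = "custom",
    params = list(k_rep_pip2 = p$k_rep, PIP2_tot = p$PIP2_tot),
    formula = "k_rep_pip2 * (PIP2_tot - PIP2)", home = compartment)
  # constitutive (receptor-independent) PLC background: carries the same
  # calcium dependence as receptor-activated PLC, normalised to 1 at basal
  # calcium so the derived rate balances degradation exactly at rest
  ca0 <- net$species$initial[net$species$name == ca_species]
  v_src <- p$v_ip3_basal
  if (is.na(v_src)) {
    deg <- ip3_balance(0, 0,
                       net$species$initial[net$species$name == "IP3_cyt"],
                       ca0, p)
    v_src <- deg$degradation_3k + deg$degradation_5p
  }
  hill_b <- ca0^p$n_plc_ca / (p$K_plc_ca^p$n_plc_ca + ca0^p$n_plc_ca)
  net <- add_reaction(net, "ip3_basal_production",
    c(IP3_cyt = 1, PIP2 = -1), law = "custom",
    params = list(v_ip3_basal = v_src, hill_plc_basal = hill_b,
                  K_plc_ca = p$K_plc_ca, n_plc_ca = p$n_plc_ca),
    formula = paste0(
      "v_ip3_basal / hill_plc_basal * ", ca_species, "^n_plc_ca / (",
      "K_plc_ca^n_plc_ca + ", ca_species, "^n_plc_ca)",
      " * PIP2 / (PIP2 + 1e-9)"),
    modifiers = ca_species, home = compartment)

  # --- IP3 degradation -----------------------------------------------------
  net <- add_reaction(net, "ip3_3kinase",
    c(IP3_cyt = -1, IP4 = 1), law = "custom",
    params = list(V3k = p$V3k, K3k_ca = p$K3k_ca, n3k = p$n3k, Km3k = p$Km3k),
    formula = paste0(
      "V3k * ", ca_species, "^n3k / (K3k_ca^n3k + ", ca_species, "^n3k)",
      " * IP3_cyt / (Km3k + IP3_cyt)"),
    modifiers = ca_species, home = compartment)
  net <- add_reaction(net, "ip3_5phosphatase",
    c(IP3_cyt = -1, IP2 = 1), law = "custom",
    params = list(V5p = p$V5p, Km5p = p$Km5p),
    formula = "V5p * IP3_cyt / (Km5p + IP3_cyt)", home = compartment)

  # metabolic clearance of the terminal products so the cascade has a true
  # steady state (DAG phosphorylation/lipase, inositol phosphatase chains)
  for (sp in c("DAG", "IP2", "IP4"))
    net <- add_reaction(net, paste0(tolower(sp), "_clearance"),
      stats::setNames(-1, sp), law = "mass_action", params = c(k = 0.5),
      home = compartment)

  net
}

#' IP3 mass balance at a point
#'
#' Net dIP3/dt (uM/s) from production by active PLC on PIP2 and degradation by
#' the Ca-dependent 3-kinase and the 5-phosphatase, using the same rate laws
#' as the assembled network.
#'
#' @param plc_star active PLC concentration, uM
#' @param pip2 PIP2 concentration, uM
#' @param ip3 IP3 concentration, uM
#' @param ca cytosolic calcium, uM
#' @param p cascade parameter list
#' @return list with \code{production}, \code{degradation_3k},
#'   \code{degradation_5p} and \code{net} (uM/s)
#' @export
ip3_balance <- function(plc_star, pip2, ip3, ca, p = mglur_params()) {
  stopifnot(plc_star >= 0, pip2 >= 0, ip3 >= 0, ca >= 0)
  v_basal <- p$v_ip3_basal
  if (is.na(v_basal)) {
    # constitutive production pinned to balance degradation at rest
    # (0.1 uM IP3, 0.06 uM Ca)
    v_basal <- p$V3k * 0.06^p$n3k / (p$K3k_ca^p$n3k + 0.06^p$n3k) *
      0.1 / (p$Km3k + 0.1) + p$V5p * 0.1 / (p$Km5p + 0.1)
  }
  # the constitutive PLC background carries the same Ca dependence as the
  # receptor-activated branch, normalised to 1 at basal (0.06 uM) calcium
  hill <- function(c) c^p$n_plc_ca / (p$K_plc_ca^p$n_plc_ca + c^p$n_plc_ca)
  prod <- p$k_pip2 * plc_star * pip2 + v_basal * hill(ca) / hill(0.06)
  d3k <- p$V3k * ca^p$n3k / (p$K3k_ca^p$n3k + ca^p$n3k) *
    ip3 / (p$Km3k + ip3)
  d5p <- p$V5p * ip3 / (p$Km5p + ip3)
  list(production = prod, degradation_3k = d3k, degradation_5p = d5p,
       net = prod - d3k - d5p)
}

#' Standalone mGluRI cascade network (receptor + G cycle + PLC/IP3 branch)
#'
#' Used for the receptor-level calibration experiments: calcium is clamped at
#' its basal value (declared as a species no reaction touches).
#'
#' @param p cascade parameters
#' @param ca_clamp clamped calcium concentration, uM
#' @return a \code{spine_network}
#' @export
build_cascade_network <- function(p = mglur_params(), ca_clamp = 0.06) {
  net <- new_network()
  net <- add_species(net, "Ca_cyt", "cytosol", ca_clamp)
  net <- add_species(net, "IP3_cyt", "cytosol", 0.1)
  add_mglur_cascade(net, p)
}

# Equilibrate the standalone cascade at zero glutamate; cached per parameter
# signature because calibration sweeps reuse it heavily.
.cascade_cache <- new.env(parent = emptyenv())

cascade_baseline <- function(net, t_eq = 20000) {
  key <- paste(vapply(net$reactions, `[[`, "", "id"), collapse = "|")
  key <- paste(key, paste(unlist(net$species$initial), collapse = ","),
               paste(format(unlist(lapply(net$reactions, `[[`, "params")),
                            digits = 12), collapse = ","), sep = "#")
  hit <- .cascade_cache[[key]]
  if (!is.null(hit)) return(hit)
  zero <- list(glu_mglur = function(t) 0)
  out <- simulate_network(net, times = c(0, t_eq / 2, t_eq), inputs = zero,
                          rtol = 1e-10, atol = 1e-14)
  st <- out[nrow(out), -1]
  .cascade_cache[[key]] <- st
  st
}

#' GalphaGTP concentration-response to sustained glutamate
#'
#' Simulates a long constant-glutamate stimulation for each concentration in
#' \code{glu_grid}, starting from the equilibrated basal state, and reports the
#' equilibrium (end-of-stimulation) GalphaGTP normalised to the basal
#' steady-state value, with a Hill fit attached.
#'
#' @param glu_grid glutamate concentrations, uM (sorted internally)
#' @param duration stimulation length, s (default 140 min)
#' @param p cascade parameters
#' @param net optional prebuilt cascade network
#' @return object of class \code{dose_response}: data.frame (\code{dose},
#'   \code{response}) with the \code{\link{fit_hill}} result as attribute
#'   \code{fit}
#' @export
galphagtp_dose_response <- function(glu_grid, duration = 140 * 60,
                                    p = mglur_params(), net = NULL) {
  if (is.unsorted(glu_grid)) {
    warning("glutamate grid not sorted; sorting")
    glu_grid <- sort(glu_grid)
  }
  if (is.null(net)) net <- build_cascade_network(p)
  base <- cascade_baseline(net)
  basal <- as.numeric(base["GaGTP"])
  resp <- vapply(glu_grid, function(conc) {
    inp <- list(glu_mglur = function(t) conc)
    out <- simulate_network(net, times = seq(0, duration, length.out = 60),
                            init = base, inputs = inp)
    as.numeric(out[nrow(out), "GaGTP"]) / basal
  }, numeric(1))
  dr <- data.frame(dose = glu_grid, response = resp)
  attr(dr, "fit") <- tryCatch(fit_hill(dr$dose, dr$response),
                              error = function(e) NULL)
  class(dr) <- c("dose_response", class(dr))
  dr
}

#' Glutamate binding concentration-response
#'
#' Fraction of receptor in glutamate-bound states at the end of a square
#' glutamate application of \code{pulse_duration} (default 10 s), versus
#' concentration; Hill fit attached.
#'
#' By default the curve is computed under the nucleotide-free condition
#' (\code{gtp_free = TRUE}): agonist binding assays on membrane preparations
#' are performed without GTP, so the agonist-receptor-G ternary complex is
#' stable and binding reports the high-affinity coupled state. With GTP
#' turnover active (as in the functional assays) nucleotide exchange strips
#' the G protein and the same receptor binds agonist with roughly tenfold
#' lower affinity.
#'
#' @inheritParams galphagtp_dose_response
#' @param pulse_duration application length, s
#' @param gtp_free disable nucleotide exchange (GTP-free binding-assay
#'   condition)
#' @return a \code{dose_response} object (see
#'   \code{\link{galphagtp_dose_response}})
#' @export
glutamate_binding_curve <- function(glu_grid, pulse_duration = 10,
                                    p = mglur_params(), net = NULL,
                                    gtp_free = TRUE) {
  glu_grid <- sort(glu_grid)
  if (gtp_free) {
    p <- utils::modifyList(p, list(k_ex_act = 0, k_ex_basal = 0))
    net <- NULL
  }
  if (is.null(net)) net <- build_cascade_network(p)
  base <- cascade_baseline(net)
  bound_states <- grep("^mLR", net$species$name, value = TRUE)
  resp <- vapply(glu_grid, function(conc) {
    inp <- list(glu_mglur = function(t) conc)
    out <- simulate_network(net,
                            times = seq(0, pulse_duration, length.out = 41),
                            init = base, inputs = inp)
    sum(out[nrow(out), bound_states]) / sum(base[grep("^m", names(base))])
  }, numeric(1))
  dr <- data.frame(dose = glu_grid, response = resp)
  attr(dr, "fit") <- tryCatch(fit_hill(dr$dose, dr$response),
                              error = function(e) NULL)
  class(dr) <- c("dose_response", class(dr))
  dr
}
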