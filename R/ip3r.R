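# De Young-Keizer type IP3 receptor gating and ER calcium fluxes.
#
# Each IP3R subunit carries three binding sites: an IP3 site (index i), an
# activating Ca site (j) and an inhibitory Ca site (k). The eight occupancy
# states x_ijk of one subunit evolve by mass-action binding/unbinding; the
# channel conducts when the required number of subunits (default 3 of 4) are
# in the open-competent state x110 (IP3 bound, activating Ca bound, free of
# inhibitory Ca), giving P_open = x110^m. The scheme satisfies detailed
# balance, so the equilibrium occupancy has the closed form used by
# ip3r_open_probability() and yields the characteristic bell-shaped Ca
# dependence peaking between 0.2 and 0.5 uM.

#' Default IP3R / ER flux parameters
#'
#' Subunit rate constants follow the canonical De Young-Keizer set
#' (a's in 1/(uM s), derived dissociation constants d's in uM):
#' d1 = 0.13, d2 = 1.049, d3 = 0.9434, d4 = 0.1445, d5 = 0.08234.
#'
#' @param ... named overrides
#' @return parameter list
#' @export
ip3r_params <- function(...) {
  p <- list(
    a1 = 400, d1 = 0.2,       # IP3 binding, inhibitory site free
                              # (Kd raised from the canonical 0.13 within the
                              # experimental 0.1-1 uM range as a calibration
                              # anchor for the calcium pulse potency)
    a2 = 0.2, d2 = 1.049,     # inhibitory Ca binding, IP3 bound
    a3 = 400, d3 = 0.2 * 1.049 / 0.1445,  # IP3 binding, inhibitory site
                              # occupied; derived from the cycle d1 d2 = d3 d4
                              # so the scheme satisfies detailed balance
                              # exactly (the canonical rounded 0.9434 violates
                              # the cycle by 4e-4)
    a4 = 0.2, d4 = 0.1445,    # inhibitory Ca binding, IP3 free
    a5 = 40,  d5 = 0.08234,   # activating Ca binding (on-rate doubled
                              # vs the canonical 20 for faster channel
                              # deactivation; equilibrium unchanged)
    n_open = 3,               # subunits required open-competent (3-of-4)
    v_ip3r = 0.70,            # max IP3R permeability, 1/s (cytosol-referenced)
    v_leak_er = NA,           # ER leak, 1/s; NA -> derived at baseline
    V_serca = 22,             # SERCA Vmax, uM/s
    K_serca = 0.2, n_serca = 2
  )
  utils::modifyList(p, list(...))
}

ip3r_state_names <- function() {
  g <- expand.grid(k = 0:1, j = 0:1, i = 0:1)
  paste0("x", g$i, g$j, g$k)
}

#' Equilibrium IP3R open probability
#'
#' Closed-form detailed-balance solution of the eight-state subunit scheme,
#' raised to the subunit requirement. Vectorised over \code{ca} and
#' \code{ip3}.
#'
#' @param ca cytosolic calcium, uM
#' @param ip3 IP3 concentration, uM
#' @param p \code{\link{ip3r_params}}
#' @return open probability in [0, 1]
#' @export
ip3r_open_probability <- function(ca, ip3, p = ip3r_params()) {
  stopifnot(all(ca >= 0), all(ip3 >= 0))
  x110 <- ip3r_subunit_equilibrium_x110(ca, ip3, p)
  x110^p$n_open
}

#' Equilibrium occupancy of the open-competent subunit state x110
#'
#' @inheritParams ip3r_open_probability
#' @return occupancy of x110 in [0, 1]
#' @export
ip3r_subunit_equilibrium_x110 <- function(ca, ip3, p = ip3r_params()) {
  # detailed balance: inhibition constant seen from the IP3-bound branch
  Q2 <- p$d2 * (ip3 + p$d1) / (ip3 + p$d3)
  (ip3 / (ip3 + p$d1)) * (ca / (ca + p$d5)) * (Q2 / (Q2 + ca))
}

#' Full equilibrium occupancy vector of one subunit
#'
#' @inheritParams ip3r_open_probability
#' @return named vector over the eight states x_ijk, summing to 1
#' @export
ip3r_subunit_equilibrium <- function(ca, ip3, p = ip3r_params()) {
  # unnormalised detailed-balance weights relative to x000: the activating
  # site contributes ca/d5 independently; the (IP3, inhibitory) pair
  # contributes 1, ip3/d1, ca/d4 or ip3*ca/(d1*d2) (both routes to the double
  # corner agree because d1 d2 = d3 d4)
  w <- numeric(8)
  names(w) <- ip3r_state_names()
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    wt <- if (j) ca / p$d5 else 1
    ik <- if (i && k) ip3 * ca / (p$d1 * p$d2)
          else if (i) ip3 / p$d1
          else if (k) ca / p$d4
          else 1
    w[paste0("x", i, j, k)] <- wt * ik
  }
  w / sum(w)
}

#' Add IP3R subunit kinetics and ER calcium fluxes to a network
#'
#' Declares the eight subunit-state fractions (initialised at their
#' equilibrium for the given basal Ca/IP3) plus the IP3R, ER-leak and SERCA
#' calcium fluxes between \code{Ca_ER} and \code{Ca_cyt}.
#'
#' @param net network declaring \code{Ca_cyt}, \code{Ca_ER}, \code{IP3_cyt}
#' @param p \code{\link{ip3r_params}}
#' @param ca_basal,ip3_basal basal concentrations used to initialise the
#'   subunit states and (if \code{v_leak_er} is NA) to derive the ER leak that
#'   balances SERCA at baseline
#' @return updated network
#' @export
add_ip3r_er <- function(net, p = ip3r_params(), ca_basal = 0.06,
                        ip3_basal = 0.1) {
  sts <- ip3r_state_names()
  x0 <- ip3r_subunit_equilibrium(ca_basal, ip3_basal, p)
  net <- add_species(net, sts, "ER", as.numeric(x0[sts]))

  add_sub_edge <- function(net, from, to, kon_expr, koff, tag, species_dep) {
    net <- add_reaction(net, paste0("ip3r_", tag, "_", from),
      stats::setNames(c(-1, 1), c(from, to)), law = "custom",
      params = stats::setNames(list(kon_expr$k), kon_expr$kname),
      formula = paste0(kon_expr$kname, " * ", species_dep, " * ", from),
      modifiers = species_dep, home = "ER")
    add_reaction(net, paste0("ip3r_", tag, "r_", to),
      stats::setNames(c(-1, 1), c(to, from)), law = "mass_action",
      params = c(k = koff), home = "ER")
  }

  for (j in 0:1) for (k in 0:1) {
    # IP3 site (i: 0 -> 1); rate depends on inhibitory site k
    a <- if (k == 0) p$a1 else p$a3
    d <- if (k == 0) p$d1 else p$d3
    net <- add_sub_edge(net, paste0("x0", j, k), paste0("x1", j, k),
      list(k = a, kname = if (k == 0) "ip3r_a1" else "ip3r_a3"),
      a * d, paste0("ip3", j, k), "IP3_cyt")
  }
  for (i in 0:1) for (k in 0:1) {
    # activating Ca site (j: 0 -> 1)
    net <- add_sub_edge(net, paste0("x", i, 0, k), paste0("x", i, 1, k),
      list(k = p$a5, kname = "ip3r_a5"),
      p$a5 * p$d5, paste0("act", i, k), "Ca_cyt")
  }
  for (i in 0:1) for (j in 0:1) {
    # inhibitory Ca site (k: 0 -> 1); rate depends on IP3 site i
    a <- if (i == 1) p$a2 else p$a4
    d <- if (i == 1) p$d2 else p$d4
    net <- add_sub_edge(net, paste0("x", i, j, 0), paste0("x", i, j, 1),
      list(k = a, kname = if (i == 1) "ip3r_a2" else "ip3r_a4"),
      a * d, paste0("inh", i, j), "Ca_cyt")
  }

  # --- ER calcium fluxes (cytosol-referenced, uM/s) ------------------------
  v_leak <- p$v_leak_er
  if (is.na(v_leak)) {
    po <- ip3r_open_probability(ca_basal, ip3_basal, p)
    serca <- p$V_serca * ca_basal^p$n_serca /
      (p$K_serca^p$n_serca + ca_basal^p$n_serca)
    er_ca <- net$species$initial[net$species$name == "Ca_ER"]
    if (!length(er_ca)) stop("Ca_ER must be declared before add_ip3r_er")
    v_leak <- serca / (er_ca - ca_basal) - p$v_ip3r * po
    if (v_leak < 0)
      stop("baseline ER balance impossible: v_ip3r too large for V_serca")
  }

  net <- add_reaction(net, "ip3r_flux",
    c(Ca_ER = -1, Ca_cyt = 1), law = "custom",
    params = list(v_ip3r = p$v_ip3r, ip3r_nopen = p$n_open),
    formula = "v_ip3r * x110^ip3r_nopen * (Ca_ER - Ca_cyt)",
    modifiers = c("x110", "Ca_ER"), home = "cytosol")
  net <- add_reaction(net, "er_leak",
    c(Ca_ER = -1, Ca_cyt = 1), law = "custom",
    params = list(v_leak_er = v_leak),
    formula = "v_leak_er * (Ca_ER - Ca_cyt)",
    modifiers = "Ca_ER", home = "cytosol")
  net <- add_reaction(net, "serca",
    c(Ca_cyt = -1, Ca_ER = 1), law = "hill",
    params = c(Vmax = p$V_serca, K = p$K_serca, n = p$n_serca,
               substrate = "Ca_cyt"), home = "cytosol")
  net
}

#' ER calcium fluxes at a state
#'
#' @param ca_cyt,ca_er,ip3 concentrations, uM
#' @param p \code{\link{ip3r_params}} (with \code{v_leak_er} resolved; if NA
#'   it is derived for a 0.06/0.1/500 uM baseline)
#' @return list with \code{J_IP3R}, \code{J_SERCA}, \code{J_leak} in uM/s,
#'   cytosol-referenced; IP3R/leak positive into the cytosol, SERCA positive
#'   into the ER
#' @export
er_calcium_fluxes <- function(ca_cyt, ca_er, ip3, p = ip3r_params()) {
  stopifnot(ca_cyt >= 0, ca_er >= 0)
  v_leak <- p$v_leak_er
  if (is.na(v_leak)) {
    po_b <- ip3r_open_probability(0.06, 0.1, p)
    serca_b <- p$V_serca * 0.06^p$n_serca /
      (p$K_serca^p$n_serca + 0.06^p$n_serca)
    v_leak <- serca_b / (500 - 0.06) - p$v_ip3r * po_b
  }
  po <- ip3r_open_probability(ca_cyt, ip3, p)
  list(
    J_IP3R = p$v_ip3r * po * (ca_er - ca_cyt),
    J_SERCA = p$V_serca * ca_cyt^p$n_serca /
      (p$K_serca^p$n_serca + ca_cyt^p$n_serca),
    J_leak = v_leak * (ca_er - ca_cyt)
  )
}
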