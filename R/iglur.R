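# Markov kinetic schemes for AMPA and NMDA receptors.
#
# Both receptors follow a five-state scheme with two sequential glutamate
# binding steps (statistical factors 2 and 1), one open state entered from
# the doubly-bound closed state, and one desensitised state:
#
#     C0 =(2 kon glu)= C1 =(kon glu)= C2 =(beta/alpha)= O
#                                     ||
#                                     D   (kd / kr)
#
# State variables are population fractions (they sum to 1). Rate constants
# are of the fast-deactivating, quickly desensitising AMPA type and of the
# slow, high-affinity NMDA type respectively (Jonas-style and
# Lester/Jahr-style magnitudes); exact values are configuration-exposed.
# The NMDA open fraction drives calcium influx into the PSD through a fixed
# driving-force flux coefficient (no membrane-voltage or Mg-block dynamics:
# the model describes biochemistry only). AMPA carries no calcium by default
# (GluA2-containing receptor assumption); a small permeability can be enabled
# in the configuration.

#' Default AMPA and NMDA receptor parameters
#'
#' Rates in 1/s, binding in 1/(uM s). \code{k_nmda_ca} is the per-receptor
#' calcium flux coefficient into the PSD (uM/s per open receptor at unit open
#' fraction), calibrated so the full model's single-release calcium peak with
#' mGluRI at 100 nm is 516 nM.
#'
#' @param ... named overrides
#' @return parameter list
#' @export
iglur_params <- function(...) {
  p <- list(
    # AMPA (fast, low-affinity, strongly desensitising)
    ampa_kon = 10, ampa_koff = 2000,      # Kd = 200 uM
    ampa_beta = 4000, ampa_alpha = 2000,
    ampa_kd = 1000, ampa_kr = 15,
    n_ampa = 80,
    ampa_ca_coef = 0,                      # GluA2-containing: Ca-impermeable
    # NMDA (slow, high-affinity)
    nmda_kon = 5, nmda_koff = 4.7,         # Kd ~ 1 uM
    nmda_beta = 50, nmda_alpha = 100,
    nmda_kd = 80, nmda_kr = 1.8,   # strong desensitisation under
                                   # sustained glutamate (tetanus-calibrated)
    n_nmda = 20,
    k_nmda_ca = 1150,                       # uM/s per receptor at open fraction 1;
                                           # jointly calibrated against the full
                                           # model's single-release (~516 nM) and
                                           # 1-s 100-Hz tetanus (~3.3 uM) calcium
                                           # peaks
    receptor_radius = 20                   # nm from the release site
  )
  utils::modifyList(p, list(...))
}

iglur_state_names <- function(prefix) paste0(prefix, c("C0", "C1", "C2", "O", "D"))

# shared builder for the five-state scheme
add_ligand_gated_scheme <- function(net, prefix, kon, koff, beta, alpha,
                                    kd, kr, glu_input, compartment = "PSD") {
  sts <- iglur_state_names(prefix)
  init <- stats::setNames(c(1, 0, 0, 0, 0), sts)
  net <- add_species(net, sts, compartment, init)
  kon_name <- paste0(prefix, "kon")
  bind <- function(net, from, to, factor, tag) {
    net <- add_reaction(net, paste0(prefix, "bind", tag),
      stats::setNames(c(-1, 1), c(from, to)), law = "custom",
      params = stats::setNames(list(kon), kon_name),
      formula = paste0(factor, " * ", kon_name, " * ", glu_input, " * ", from),
      modifiers = glu_input, home = compartment)
    net
  }
  net <- bind(net, sts[1], sts[2], 2, "1")
  net <- bind(net, sts[2], sts[3], 1, "2")
  net <- add_reaction(net, paste0(prefix, "unbind1"),
    stats::setNames(c(-1, 1), c(sts[2], sts[1])), law = "mass_action",
    params = c(k = koff), home = compartment)
  net <- add_reaction(net, paste0(prefix, "unbind2"),
    stats::setNames(c(-1, 1), c(sts[3], sts[2])), law = "mass_action",
    params = c(k = 2 * koff), home = compartment)
  net <- add_reaction(net, paste0(prefix, "open"),
    stats::setNames(c(-1, 1), c(sts[3], sts[4])), law = "mass_action",
    params = c(k = beta), home = compartment)
  net <- add_reaction(net, paste0(prefix, "close"),
    stats::setNames(c(-1, 1), c(sts[4], sts[3])), law = "mass_action",
    params = c(k = alpha), home = compartment)
  net <- add_reaction(net, paste0(prefix, "desens"),
    stats::setNames(c(-1, 1), c(sts[3], sts[5])), law = "mass_action",
    params = c(k = kd), home = compartment)
  net <- add_reaction(net, paste0(prefix, "resens"),
    stats::setNames(c(-1, 1), c(sts[5], sts[3])), law = "mass_action",
    params = c(k = kr), home = compartment)
  net
}

#' Add AMPA and NMDA receptor schemes to a network
#'
#' State fractions live in the PSD compartment and are driven by the
#' glutamate input named \code{glu_input} (concentration at the receptor
#' cluster, 20 nm from the release site). The NMDA open fraction feeds a
#' calcium source into \code{Ca_psd}; AMPA contributes calcium only if
#' \code{ampa_ca_coef > 0}.
#'
#' @param net network declaring \code{Ca_psd}
#' @param p \code{\link{iglur_params}}
#' @param glu_input name of the glutamate forcing input
#' @return updated network
#' @export
add_iglur <- function(net, p = iglur_params(), glu_input = "glu_psd") {
  net <- add_ligand_gated_scheme(net, "ampa_", p$ampa_kon, p$ampa_koff,
    p$ampa_beta, p$ampa_alpha, p$ampa_kd, p$ampa_kr, glu_input)
  net <- add_ligand_gated_scheme(net, "nmda_", p$nmda_kon, p$nmda_koff,
    p$nmda_beta, p$nmda_alpha, p$nmda_kd, p$nmda_kr, glu_input)
  net <- add_reaction(net, "nmda_ca_influx",
    c(Ca_psd = 1), law = "custom",
    params = list(k_nmda_ca = p$k_nmda_ca, n_nmda = p$n_nmda),
    formula = "k_nmda_ca * n_nmda * nmda_O",
    modifiers = "nmda_O", home = "PSD")
  if (p$ampa_ca_coef > 0) {
    net <- add_reaction(net, "ampa_ca_influx",
      c(Ca_psd = 1), law = "custom",
      params = list(ampa_ca_coef = p$ampa_ca_coef, n_ampa = p$n_ampa),
      formula = "ampa_ca_coef * n_ampa * ampa_O",
      modifiers = "ampa_O", home = "PSD")
  }
  net
}

#' NMDA calcium flux into the PSD
#'
#' Linear in both the open fraction and the receptor count:
#' \code{k_nmda_ca * n_receptors * open_fraction} uM/s deposited in the PSD.
#'
#' @param open_fraction NMDA open fraction in [0, 1]
#' @param n_receptors receptor count
#' @param p \code{\link{iglur_params}}
#' @return flux, uM/s
#' @export
nmda_calcium_flux <- function(open_fraction, n_receptors = 20,
                              p = iglur_params()) {
  stopifnot(all(open_fraction >= 0), all(open_fraction <= 1), n_receptors >= 0)
  p$k_nmda_ca * n_receptors * open_fraction
}

#' Rate matrix of a receptor scheme at clamped glutamate
#'
#' Generator matrix Q (columns = from-state) of the five-state scheme, used
#' for stationary-distribution and matrix-exponential cross-checks.
#'
#' @param glu clamped glutamate concentration, uM
#' @param p \code{\link{iglur_params}}
#' @param receptor \code{"ampa"} or \code{"nmda"}
#' @return 5x5 matrix with state dimnames
#' @export
iglur_rate_matrix <- function(glu, p = iglur_params(),
                              receptor = c("ampa", "nmda")) {
  receptor <- match.arg(receptor)
  g <- function(nm) p[[paste0(receptor, "_", nm)]]
  sts <- iglur_state_names(paste0(receptor, "_"))
  Q <- matrix(0, 5, 5, dimnames = list(sts, sts))
  add <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  add(sts[1], sts[2], 2 * g("kon") * glu)
  add(sts[2], sts[1], g("koff"))
  add(sts[2], sts[3], g("kon") * glu)
  add(sts[3], sts[2], 2 * g("koff"))
  add(sts[3], sts[4], g("beta"))
  add(sts[4], sts[3], g("alpha"))
  add(sts[3], sts[5], g("kd"))
  add(sts[5], sts[3], g("kr"))
  Q
}

#' Simulate receptor open fractions for a glutamate trace
#'
#' Integrates the two schemes alone (no calcium coupling) for a given
#' glutamate forcing, returning open-fraction time series.
#'
#' @param glu_fun function(t) -> glutamate uM at the receptor cluster
#' @param times output time grid, s
#' @param p \code{\link{iglur_params}}
#' @param restart_at solver restart times (stimulus onsets)
#' @return data.frame time, ampa_open, nmda_open
#' @export
iglur_response <- function(glu_fun, times, p = iglur_params(),
                           restart_at = numeric(0)) {
  net <- new_network()
  net <- add_species(net, "Ca_psd", "PSD", 0)
  net <- add_iglur(net, p)
  out <- simulate_network(net, times, inputs = list(glu_psd = glu_fun),
                          restart_at = restart_at, atol = 1e-10)
  data.frame(time = out[, "time"], ampa_open = out[, "ampa_O"],
             nmda_open = out[, "nmda_O"])
}
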