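# Plasma-membrane calcium extrusion, cytosolic/PSD buffering and
# PSD <-> cytosol diffusive exchange.
#
# Cytosolic calcium is extruded by PMCA (high-affinity, Hill n = 2) and NCX
# (low-affinity, Hill n = 1) and re-enters through a passive plasma-membrane
# leak driven by the cleft -> cytosol gradient. The synaptic cleft is treated
# as a clamped 2 mM reservoir (its volume is tiny but the model keeps a fixed
# extracellular baseline and no cleft calcium dynamics). The plasma leak is
# derived at assembly so the pumps and leak balance exactly at the basal
# cytosolic calcium. Calmodulin, calcineurin and PKC act purely as bimolecular
# Ca buffers in both cytosol and PSD (no downstream enzymatic signalling).
# Ca and IP3 exchange between PSD and cytosol by amount-conserving
# first-order diffusion.

#' Default calcium-homeostasis parameters
#'
#' Pumps in uM/s (Vmax) and uM (half-activation); buffer totals in uM with
#' on-rates in 1/(uM s) and dissociation constants in uM; exchange rates in
#' um^3/s (amount flux per uM gradient).
#'
#' @param ... named overrides
#' @return parameter list
#' @export
calcium_params <- function(...) {
  p <- list(
    ca_basal = 0.06, ca_cleft = 2000, ca_er = 500,
    V_pmca = 7, K_pmca = 0.25, n_pmca = 2,
    V_ncx = 14, K_ncx = 1, n_ncx = 1,
    v_leak_pm = NA,                    # derived at baseline if NA, 1/s
    # buffers: total, kon, Kd  (bimolecular, 1:1)
    buffers = list(
      CaM = list(total = 25, kon = 50, Kd = 2),
      CaN = list(total = 1,  kon = 10, Kd = 0.1),
      PKC = list(total = 1,  kon = 10, Kd = 0.5)
    ),
    psd_buffer_scale = 1,              # PSD buffer totals relative to cytosol
    k_ca_psd_cyt = 0.06,               # Ca exchange conductance, um^3/s
    k_ip3_psd_cyt = 0.004              # IP3 exchange conductance, um^3/s
  )
  utils::modifyList(p, list(...))
}

# net plasma-membrane calcium flux (uM/s, cytosol-referenced) at given
# cytosolic and cleft calcium, with leak coefficient resolved
pm_flux_terms <- function(ca_cyt, ca_cleft, p, v_leak) {
  pmca <- p$V_pmca * ca_cyt^p$n_pmca / (p$K_pmca^p$n_pmca + ca_cyt^p$n_pmca)
  ncx <- p$V_ncx * ca_cyt^p$n_ncx / (p$K_ncx^p$n_ncx + ca_cyt^p$n_ncx)
  leak <- v_leak * (ca_cleft - ca_cyt)
  list(pmca = pmca, ncx = ncx, leak = leak, net = leak - pmca - ncx)
}

resolve_pm_leak <- function(p) {
  if (!is.na(p$v_leak_pm)) return(p$v_leak_pm)
  f <- pm_flux_terms(p$ca_basal, p$ca_cleft, p, 0)
  (f$pmca + f$ncx) / (p$ca_cleft - p$ca_basal)
}

#' Net plasma-membrane calcium flux
#'
#' \code{leak_in - PMCA_out - NCX_out} in uM/s (cytosol-referenced). With the
#' default derived leak the net flux is exactly zero at the basal pair
#' (0.06 uM cytosol, 2 mM cleft).
#'
#' @param ca_cyt cytosolic calcium, uM
#' @param ca_cleft cleft (extracellular) calcium, uM
#' @param p \code{\link{calcium_params}}
#' @return net flux, uM/s
#' @export
plasma_membrane_fluxes <- function(ca_cyt, ca_cleft, p = calcium_params()) {
  stopifnot(all(ca_cyt >= 0), all(ca_cleft >= 0))
  v_leak <- resolve_pm_leak(p)
  pm_flux_terms(ca_cyt, ca_cleft, p, v_leak)$net
}

#' Add calcium homeostasis to a network
#'
#' Declares \code{Ca_cyt}, \code{Ca_psd}, \code{Ca_ER} and the clamped
#' \code{Ca_cleft}, the PMCA/NCX/leak plasma-membrane fluxes, the six buffer
#' pairs (three buffers in cytosol and PSD, initialised at binding
#' equilibrium) and the PSD <-> cytosol exchange of Ca and IP3.
#'
#' @param net a network already declaring \code{IP3_cyt} (and \code{IP3_psd}
#'   is declared here)
#' @param p \code{\link{calcium_params}}
#' @return updated network
#' @export
add_calcium_homeostasis <- function(net, p = calcium_params()) {
  ca0 <- p$ca_basal
  net <- add_species(net, c("Ca_cyt", "Ca_psd", "Ca_ER", "Ca_cleft"),
                     c("cytosol", "PSD", "ER", "cleft"),
                     c(ca0, ca0, p$ca_er, p$ca_cleft))
  ip30 <- net$species$initial[net$species$name == "IP3_cyt"]
  net <- add_species(net, "IP3_psd", "PSD", ip30)

  v_leak <- resolve_pm_leak(p)
  net <- add_reaction(net, "pmca",
    c(Ca_cyt = -1), law = "hill",
    params = c(Vmax = p$V_pmca, K = p$K_pmca, n = p$n_pmca,
               substrate = "Ca_cyt"), home = "cytosol")
  net <- add_reaction(net, "ncx",
    c(Ca_cyt = -1), law = "hill",
    params = c(Vmax = p$V_ncx, K = p$K_ncx, n = p$n_ncx,
               substrate = "Ca_cyt"), home = "cytosol")
  net <- add_reaction(net, "pm_leak",
    c(Ca_cyt = 1), law = "custom",
    params = list(v_leak_pm = v_leak),
    formula = "v_leak_pm * (Ca_cleft - Ca_cyt)",
    modifiers = "Ca_cleft", home = "cytosol")

  # buffers in cytosol and PSD, initialised at the binding isotherm
  for (cmp in c("cytosol", "PSD")) {
    sfx <- if (cmp == "cytosol") "cyt" else "psd"
    scl <- if (cmp == "cytosol") 1 else p$psd_buffer_scale
    for (bn in names(p$buffers)) {
      b <- p$buffers[[bn]]
      tot <- b$total * scl
      bound0 <- tot * ca0 / (ca0 + b$Kd)
      free_nm <- paste0(bn, "_", sfx)
      bound_nm <- paste0("Ca", bn, "_", sfx)
      ca_nm <- paste0("Ca_", sfx)
      net <- add_species(net, c(free_nm, bound_nm), cmp,
                         c(tot - bound0, bound0))
      net <- add_reaction(net, paste0("buf_on_", bn, "_", sfx),
        stats::setNames(c(-1, -1, 1), c(ca_nm, free_nm, bound_nm)),
        law = "mass_action", params = c(k = b$kon), home = cmp)
      net <- add_reaction(net, paste0("buf_off_", bn, "_", sfx),
        stats::setNames(c(-1, 1, 1), c(bound_nm, ca_nm, free_nm)),
        law = "mass_action", params = c(k = b$kon * b$Kd), home = cmp)
    }
  }

  # PSD <-> cytosol exchange; conductance in um^3/s so the reaction rate
  # (referenced to the PSD compartment) is k/V_psd * (c_psd - c_cyt)
  vpsd <- net$compartments$volume[net$compartments$name == "PSD"]
  net <- add_reaction(net, "ca_psd_cyt_exchange",
    c(Ca_psd = -1, Ca_cyt = 1), law = "custom",
    params = list(kx_ca = p$k_ca_psd_cyt / vpsd),
    formula = "kx_ca * (Ca_psd - Ca_cyt)",
    modifiers = "Ca_cyt", home = "PSD")
  net <- add_reaction(net, "ip3_psd_cyt_exchange",
    c(IP3_psd = -1, IP3_cyt = 1), law = "custom",
    params = list(kx_ip3 = p$k_ip3_psd_cyt / vpsd),
    formula = "kx_ip3 * (IP3_psd - IP3_cyt)",
    modifiers = "IP3_cyt", home = "PSD")
  net
}

#' Buffer binding rates at a state
#'
#' Simple bimolecular binding for each buffer: on-flux kon*Ca*B_free, off-flux
#' kon*Kd*B_bound.
#'
#' @param ca free calcium, uM
#' @param free named vector of free buffer concentrations, uM
#' @param bound named vector of bound buffer concentrations, uM (same names)
#' @param p \code{\link{calcium_params}}
#' @return data.frame per buffer: on, off, net (uM/s, net = binding rate)
#' @export
buffer_derivatives <- function(ca, free, bound, p = calcium_params()) {
  stopifnot(ca >= 0, all(free >= 0), all(bound >= 0))
  bn <- names(p$buffers)
  on <- vapply(bn, function(b) p$buffers[[b]]$kon * ca * free[[b]], 0)
  off <- vapply(bn, function(b)
    p$buffers[[b]]$kon * p$buffers[[b]]$Kd * bound[[b]], 0)
  data.frame(buffer = bn, on = on, off = off, net = on - off,
             row.names = NULL)
}

#' Amount-conserving two-compartment exchange fluxes
#'
#' First-order diffusive exchange between PSD and cytosol: the amount flux is
#' \code{k * (c_psd - c_cyt)} (um^3/s * uM = amount/s), so concentrations
#' relax with rate \code{k (1/V_psd + 1/V_cyt)} toward equality while the
#' total amount \code{V_psd c_psd + V_cyt c_cyt} is invariant.
#'
#' @param psd_conc,cyto_conc concentrations, uM
#' @param k exchange conductance, um^3/s
#' @param v_psd,v_cyt compartment volumes, um^3
#' @return list with \code{dpsd}, \code{dcyt} (uM/s)
#' @export
intercompartment_exchange <- function(psd_conc, cyto_conc, k,
                                      v_psd = 0.002, v_cyt = 0.02) {
  stopifnot(k >= 0, v_psd > 0, v_cyt > 0)
  amt <- k * (psd_conc - cyto_conc)
  list(dpsd = -amt / v_psd, dcyt = amt / v_cyt)
}
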