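# Fixture generators: tiny networks and synthetic curves with closed-form
# answers, used to validate the engine and the fitters. The analytic answer
# is always computed from the closed form, never from the simulator.

#' Generate a validation fixture
#'
#' Kinds:
#' \describe{
#'   \item{exp_decay_network}{one-species decay A -> 0 at a given rate; analytic
#'     trajectory \code{A0 exp(-k t)}.}
#'   \item{binding_isotherm}{bimolecular binding with excess ligand; analytic
#'     equilibrium bound fraction \code{c / (c + Kd)}.}
#'   \item{hill_curve}{noiseless 4-parameter logistic samples with known
#'     EC50/n/top/bottom.}
#'   \item{two_box_exchange}{first-order exchange between two volumes;
#'     analytic relaxation rate \code{k (1/V1 + 1/V2)} toward the
#'     amount-weighted mean.}
#' }
#'
#' @param kind fixture kind (see Details)
#' @param ... kind-specific parameters (\code{rate}, \code{A0}, \code{Kd},
#'   \code{ec50}, \code{n}, \code{top}, \code{bottom}, \code{k_ex},
#'   \code{v1}, \code{v2}, \code{c1}, \code{c2})
#' @return list with the fixture inputs and an \code{analytic} element
#'   holding the closed-form expected result
#' @export
make_fixture <- function(kind = c("exp_decay_network", "binding_isotherm",
                                  "hill_curve", "two_box_exchange"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  g <- function(nm, dflt) if (!is.null(args[[nm]])) args[[nm]] else dflt
  switch(kind,
    exp_decay_network = {
      k <- g("rate", 1); A0 <- g("A0", 1)
      net <- new_network()
      net <- add_species(net, "A", "cytosol", A0)
      net <- add_reaction(net, "decay", c(A = -1), law = "mass_action",
                          params = c(k = k))
      list(kind = kind, network = net,
           analytic = function(t) A0 * exp(-k * t))
    },
    binding_isotherm = {
      Kd <- g("Kd", 0.5); kon <- g("kon", 10)
      net <- new_network()
      # ligand treated as clamped (in vast excess), receptor binds it
      net <- add_species(net, c("L", "R", "LR"), "cytosol",
                         c(g("L0", 1), g("R0", 1), 0))
      net <- add_reaction(net, "on", c(R = -1, LR = 1), law = "custom",
                          params = list(kon_fix = kon),
                          formula = "kon_fix * L * R")
      net <- add_reaction(net, "off", c(LR = -1, R = 1), law = "mass_action",
                          params = c(k = kon * Kd))
      list(kind = kind, network = net, Kd = Kd,
           analytic = function(conc) conc / (conc + Kd))
    },
    hill_curve = {
      ec50 <- g("ec50", 2); n <- g("n", 1)
      top <- g("top", 1); bottom <- g("bottom", 0)
      dose <- g("dose", 10^seq(-2, 2, length.out = 12) * ec50)
      resp <- bottom + (top - bottom) / (1 + (ec50 / dose)^n)
      list(kind = kind, dose = dose, response = resp,
           analytic = list(ec50 = ec50, n = n, top = top, bottom = bottom))
    },
    two_box_exchange = {
      k <- g("k_ex", 0.01); v1 <- g("v1", 0.002); v2 <- g("v2", 0.02)
      c1 <- g("c1", 1); c2 <- g("c2", 0)
      rate <- k * (1 / v1 + 1 / v2)
      cinf <- (v1 * c1 + v2 * c2) / (v1 + v2)
      list(kind = kind, k_ex = k, v1 = v1, v2 = v2, c1 = c1, c2 = c2,
           analytic = function(t) list(
             c1 = cinf + (c1 - cinf) * exp(-rate * t),
             c2 = cinf + (c2 - cinf) * exp(-rate * t),
             rate = rate, c_inf = cinf))
    })
}
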