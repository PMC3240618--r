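# Shared helpers: small networks and cached expensive model objects.

toy_ab_network <- function(k = 2) {
  net <- new_network()
  net <- add_species(net, c("A", "B"), "cytosol", c(1, 0))
  add_reaction(net, "a_to_b", c(A = -1, B = 1), law = "mass_action",
               params = c(k = k))
}

toy_reversible_network <- function(kon = 3, koff = 1.5) {
  net <- new_network()
  net <- add_species(net, c("Glu", "R", "GluR"), "cytosol", c(1, 1, 0))
  net <- add_reaction(net, "bind", c(Glu = -1, R = -1, GluR = 1),
                      law = "mass_action", params = c(k = kon))
  add_reaction(net, "unbind", c(GluR = -1, Glu = 1, R = 1),
               law = "mass_action", params = c(k = koff))
}

# Independent brute-force derivative oracle: per-reaction rate evaluation and
# summation, written against the declarative reaction list (not the compiled
# path used by network_derivative).
oracle_derivative <- function(net, state, t = 0, inputs = list()) {
  sp <- net$species
  vol <- net$compartments$volume[match(sp$compartment,
                                       net$compartments$name)]
  names(vol) <- sp$name
  y <- state[sp$name]
  env <- as.list(y)
  env$t <- t
  for (nm in names(inputs)) env[[nm]] <- inputs[[nm]](t)
  dy <- stats::setNames(rep(0, nrow(sp)), sp$name)
  for (r in net$reactions) {
    env2 <- env
    for (nm in names(r$params))
      if (is.numeric(r$params[[nm]])) env2[[nm]] <- r$params[[nm]]
    rate <- switch(r$law,
      mass_action = {
        reac <- r$stoich[r$stoich < 0]
        as.numeric(r$params[["k"]]) *
          prod(unlist(env[names(reac)])^(-as.numeric(reac)))
      },
      michaelis_menten = {
        s <- if ("substrate" %in% names(r$params))
          env[[as.character(r$params[["substrate"]])]]
        else env[[names(r$stoich)[r$stoich < 0][1]]]
        as.numeric(r$params[["Vmax"]]) * s /
          (as.numeric(r$params[["Km"]]) + s)
      },
      hill = {
        s <- if ("substrate" %in% names(r$params))
          env[[as.character(r$params[["substrate"]])]]
        else env[[names(r$stoich)[r$stoich < 0][1]]]
        V <- as.numeric(r$params[["Vmax"]])
        K <- as.numeric(r$params[["K"]]); n <- as.numeric(r$params[["n"]])
        V * s^n / (K^n + s^n)
      },
      custom = eval(parse(text = r$formula), envir = env2))
    vhome <- net$compartments$volume[net$compartments$name == r$home]
    for (nm in names(r$stoich))
      dy[nm] <- dy[nm] + r$stoich[[nm]] * rate * vhome / vol[nm]
  }
  dy
}

# cached heavyweight objects shared across test files
.test_cache <- new.env(parent = emptyenv())

cached <- function(tag, expr) {
  if (is.null(.test_cache[[tag]])) .test_cache[[tag]] <- force(expr)
  .test_cache[[tag]]
}

mglur_spine_model <- function() {
  cached("mglur_spine_model", {
    cfg <- spine_config()
    cfg$simulation$receptors <- "mglur"
    assemble_spine_model(cfg)
  })
}

mglur_spine_baseline <- function() {
  cached("mglur_spine_baseline", equilibrate(mglur_spine_model()))
}

spine_calibration_run <- function() {
  cached("spine_calibration_run", {
    run_protocol(mglur_spine_model(),
                 make_protocol("pulses", frequency = 50, n_pulses = 5),
                 duration = 8, baseline = mglur_spine_baseline())
  })
}
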