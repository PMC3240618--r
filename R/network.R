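# Compartmental reaction-network core: species/reaction containers, ODE
# right-hand-side assembly, conservation-law extraction, and a deSolve-based
# trajectory integrator. All concentrations are in uM, time in s, compartment
# volumes in um^3. Reaction rates are expressed in uM/s referenced to the
# reaction's "home" compartment; species in other compartments see the flux
# scaled by V_home / V_species so that amounts (not concentrations) balance.

#' Avogadro conversion factor: molecules per um^3 at 1 uM
#'
#' 1 uM = 1e-6 mol/L = 602.214 molecules per cubic micrometre. Used to convert
#' released molecule counts into concentrations.
#' @keywords internal
MOLEC_PER_UM3_PER_UM <- 602.2140857

#' Convert a molecule count in a compartment volume to a concentration
#'
#' @param n number of molecules
#' @param volume compartment volume in um^3
#' @return concentration in uM
#' @export
molecules_to_uM <- function(n, volume) {
  stopifnot(volume > 0)
  n / (MOLEC_PER_UM3_PER_UM * volume)
}

#' Default spine compartments
#'
#' The four well-mixed compartments of the model with their volumes in um^3:
#' synaptic cleft 0.0015, postsynaptic density (PSD) 0.002, cytosol 0.02 and
#' endoplasmic reticulum (ER) 0.002.
#'
#' @return data.frame with columns \code{name} and \code{volume}
#' @export
spine_compartments <- function() {
  data.frame(
    name = c("cleft", "PSD", "cytosol", "ER"),
    volume = c(0.0015, 0.002, 0.02, 0.002),
    stringsAsFactors = FALSE
  )
}

#' Create an empty reaction network
#'
#' @param compartments data.frame with columns \code{name}, \code{volume}
#'   (um^3); defaults to \code{\link{spine_compartments}}.
#' @return object of class \code{spine_network}
#' @export
new_network <- function(compartments = spine_compartments()) {
  stopifnot(is.data.frame(compartments),
            all(c("name", "volume") %in% names(compartments)))
  if (any(compartments$volume <= 0))
    stop("compartment volumes must be positive")
  if (anyDuplicated(compartments$name))
    stop("duplicate compartment names")
  structure(list(
    compartments = compartments,
    species = data.frame(name = character(), compartment = character(),
                         initial = numeric(), stringsAsFactors = FALSE),
    reactions = list(),
    compiled = NULL
  ), class = "spine_network")
}

#' Add species to a network
#'
#' @param net a \code{spine_network}
#' @param name character vector of unique species identifiers
#' @param compartment compartment name(s), recycled
#' @param initial initial concentration(s) in uM, recycled
#' @return the updated network
#' @export
add_species <- function(net, name, compartment, initial = 0) {
  stopifnot(inherits(net, "spine_network"))
  k <- length(name)
  compartment <- rep_len(compartment, k)
  initial <- rep_len(initial, k)
  if (any(initial < 0)) stop("initial concentrations must be >= 0")
  bad <- setdiff(compartment, net$compartments$name)
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  clash <- intersect(name, net$species$name)
  if (length(clash)) stop("species already declared: ", paste(clash, collapse = ", "))
  net$species <- rbind(net$species, data.frame(
    name = name, compartment = compartment, initial = initial,
    stringsAsFactors = FALSE))
  net$compiled <- NULL
  net
}

#' Add a reaction to a network
#'
#' Rate laws:
#' \describe{
#'   \item{mass_action}{rate = \code{k} times the product of reactant
#'     concentrations raised to their stoichiometric orders (reactants are the
#'     species with negative stoichiometry).}
#'   \item{michaelis_menten}{rate = \code{Vmax * S / (Km + S)} with substrate
#'     \code{S} named in \code{params["substrate"]} (or the single reactant).}
#'   \item{hill}{rate = \code{Vmax * S^n / (K^n + S^n)}.}
#'   \item{custom}{an explicit rate formula string evaluated in an environment
#'     binding every species concentration by name, every parameter, every
#'     model input (e.g. a glutamate forcing value), and \code{t}.}
#' }
#'
#' @param net a \code{spine_network}
#' @param id unique reaction identifier
#' @param stoich named numeric vector, species -> signed stoichiometry
#' @param law one of \code{"mass_action"}, \code{"michaelis_menten"},
#'   \code{"hill"}, \code{"custom"}
#' @param params named numeric parameter vector (character entries allowed for
#'   \code{substrate})
#' @param home home compartment of the rate expression; defaults to the
#'   compartment of the first reactant (or first product for pure sources)
#' @param formula rate formula string, required for \code{law = "custom"}
#' @param modifiers character vector of species/input names the rate depends
#'   on beyond its reactants (documentation and validation aid)
#' @return the updated network
#' @export
add_reaction <- function(net, id, stoich, law = "mass_action",
                         params = numeric(), home = NULL, formula = NULL,
                         modifiers = character()) {
  stopifnot(inherits(net, "spine_network"))
  law <- match.arg(law, c("mass_action", "michaelis_menten", "hill", "custom"))
  if (id %in% vapply(net$reactions, `[[`, "", "id"))
    stop("duplicate reaction id: ", id)
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("stoich must be a fully named vector")
  unknown <- setdiff(names(stoich), net$species$name)
  if (length(unknown))
    stop("reaction ", id, " references undeclared species: ",
         paste(unknown, collapse = ", "))
  unknown_mod <- setdiff(modifiers, net$species$name)
  # modifiers may also name model inputs (forcings); those are not declared as
  # species, so only warn-level validation is possible at simulation time
  if (law == "custom" && is.null(formula))
    stop("custom rate law requires a formula string")
  if (law == "mass_action" && !("k" %in% names(params)))
    stop("mass_action reaction ", id, " is missing parameter 'k'")
  if (law == "michaelis_menten" && !all(c("Vmax", "Km") %in% names(params)))
    stop("michaelis_menten reaction ", id, " is missing Vmax/Km")
  if (law == "hill" && !all(c("Vmax", "K", "n") %in% names(params)))
    stop("hill reaction ", id, " is missing Vmax/K/n")
  if (is.null(home)) {
    reac <- names(stoich)[stoich < 0]
    ref <- if (length(reac)) reac[1] else names(stoich)[1]
    home <- net$species$compartment[match(ref, net$species$name)]
  }
  if (!home %in% net$compartments$name)
    stop("unknown home compartment: ", home)
  net$reactions[[length(net$reactions) + 1L]] <- list(
    id = id, stoich = stoich, law = law, params = params, home = home,
    formula = formula, modifiers = modifiers,
    unknown_modifiers = unknown_mod)
  net$compiled <- NULL
  net
}

# Precompute index structures and rate closures for fast derivative evaluation.
compile_network <- function(net) {
  sp <- net$species
  n <- nrow(sp)
  vol <- net$compartments$volume[match(sp$compartment, net$compartments$name)]
  names(vol) <- sp$name
  idx <- seq_len(n)
  names(idx) <- sp$name

  rx <- lapply(net$reactions, function(r) {
    si <- idx[names(r$stoich)]
    vhome <- net$compartments$volume[match(r$home, net$compartments$name)]
    # concentration change of species i per unit rate: nu_i * Vhome / V_i
    scale <- as.numeric(r$stoich) * vhome / vol[si]
    reac_i <- si[r$stoich < 0]
    reac_ord <- -r$stoich[r$stoich < 0]
    law <- r$law
    p <- r$params
    rate_fn <- switch(law,
      mass_action = {
        k <- as.numeric(p[["k"]])
        ri <- as.integer(reac_i); ro <- as.numeric(reac_ord)
        function(y, env) k * prod(y[ri]^ro)
      },
      michaelis_menten = {
        subs <- if ("substrate" %in% names(p)) as.character(p[["substrate"]])
                else names(reac_i)[1]
        si2 <- as.integer(idx[subs])
        Vmax <- as.numeric(p[["Vmax"]]); Km <- as.numeric(p[["Km"]])
        function(y, env) Vmax * y[si2] / (Km + y[si2])
      },
      hill = {
        subs <- if ("substrate" %in% names(p)) as.character(p[["substrate"]])
                else names(reac_i)[1]
        si2 <- as.integer(idx[subs])
        Vmax <- as.numeric(p[["Vmax"]]); K <- as.numeric(p[["K"]])
        nh <- as.numeric(p[["n"]])
        function(y, env) {
          s <- y[si2]^nh
          Vmax * s / (K^nh + s)
        }
      },
      custom = {
        expr <- parse(text = r$formula)[[1]]
        pnum <- p[vapply(p, is.numeric, TRUE)]
        function(y, env) {
          eval(expr, envir = env)
        }
      }
    )
    list(id = r$id, si = as.integer(si), scale = as.numeric(scale),
         rate_fn = rate_fn, law = law,
         params = p, formula = r$formula)
  })

  custom_params <- list()
  for (r in net$reactions) {
    if (r$law == "custom") {
      pn <- r$params[vapply(r$params, function(z) is.numeric(z) || is.character(z), TRUE)]
      for (nm in names(pn)) custom_params[[nm]] <- r$params[[nm]]
    }
  }

  net$compiled <- list(n = n, idx = idx, vol = vol, rx = rx,
                       custom_params = custom_params)
  net
}

# Build the evaluation environment shared by all custom rate laws.
make_rate_env <- function(compiled) {
  env <- new.env(parent = baseenv())
  for (nm in names(compiled$custom_params))
    assign(nm, compiled$custom_params[[nm]], envir = env)
  env
}

#' Network time-derivative (ODE right-hand side)
#'
#' Computes d(state)/dt in uM/s for every species. Cross-compartment reactions
#' conserve amount: a rate r (uM/s in the home compartment) changes species i
#' by \code{nu_i * r * V_home / V_i}.
#'
#' @param net a \code{spine_network}
#' @param state named (or network-ordered) nonnegative concentration vector, uM
#' @param t time in s
#' @param inputs named list of forcing functions of time (e.g. glutamate
#'   concentration at a receptor location); their values at \code{t} are bound
#'   by name in custom rate formulas
#' @param neg_tol most negative concentration tolerated from an adaptive
#'   integrator probe before an error is raised; values in \code{(-neg_tol, 0)}
#'   are clamped to 0 for rate evaluation
#' @return named numeric vector of rates, uM/s
#' @export
network_derivative <- function(net, state, t = 0, inputs = list(),
                               neg_tol = 1e-3) {
  if (is.null(net$compiled)) net <- compile_network(net)
  rhs <- network_rhs(net, inputs, neg_tol = neg_tol)
  out <- rhs(t, as.numeric(state_in_order(net, state)), NULL)[[1]]
  names(out) <- net$species$name
  out
}

# Reorder a (possibly named) state vector into network species order.
state_in_order <- function(net, state) {
  sp <- net$species$name
  if (!is.null(names(state)) && all(sp %in% names(state))) state[sp]
  else if (length(state) == length(sp)) state
  else stop("state dimension/names do not match network species")
}

#' Build a deSolve-compatible RHS closure for a network
#'
#' @inheritParams network_derivative
#' @return function(t, y, parms) -> list(dy)
#' @export
network_rhs <- function(net, inputs = list(), neg_tol = 1e-3) {
  if (is.null(net$compiled)) net <- compile_network(net)
  cm <- net$compiled
  n <- cm$n
  rx <- cm$rx
  env <- make_rate_env(cm)
  sp_names <- net$species$name
  input_names <- names(inputs)
  has_custom <- any(vapply(rx, function(r) r$law == "custom", TRUE))
  nrx <- length(rx)

  function(t, y, parms) {
    if (any(y < -neg_tol))
      stop("negative concentration beyond tolerance at t=", signif(t, 6),
           " (species ", sp_names[which.min(y)], " = ", min(y), ")")
    y[y < 0] <- 0
    if (has_custom) {
      for (i in seq_len(n)) assign(sp_names[i], y[i], envir = env)
      assign("t", t, envir = env)
      for (nm in input_names) assign(nm, inputs[[nm]](t), envir = env)
    }
    dy <- numeric(n)
    for (j in seq_len(nrx)) {
      r <- rx[[j]]
      v <- r$rate_fn(y, env)
      if (v != 0) dy[r$si] <- dy[r$si] + r$scale * v
    }
    list(dy)
  }
}

#' Per-reaction rates at a state
#'
#' Mainly a diagnostic/validation aid: returns the raw rate of every reaction
#' (uM/s in each reaction's home compartment).
#'
#' @inheritParams network_derivative
#' @return named numeric vector, one entry per reaction id
#' @export
reaction_rates <- function(net, state, t = 0, inputs = list()) {
  if (is.null(net$compiled)) net <- compile_network(net)
  cm <- net$compiled
  y <- as.numeric(state_in_order(net, state))
  y[y < 0] <- 0
  env <- make_rate_env(cm)
  for (i in seq_len(cm$n)) assign(net$species$name[i], y[i], envir = env)
  assign("t", t, envir = env)
  for (nm in names(inputs)) assign(nm, inputs[[nm]](t), envir = env)
  out <- vapply(cm$rx, function(r) r$rate_fn(y, env), numeric(1))
  names(out) <- vapply(cm$rx, `[[`, "", "id")
  out
}

#' Conservation laws (conserved moieties) of a network
#'
#' Finds a basis of the left null space of the stoichiometry matrix. Each
#' returned vector \code{w} (named by species) defines a conserved amount
#' \code{sum_i w_i * V_i * c_i} whose time derivative is identically zero for
#' any rate values, because column scaling by home volumes does not change the
#' left null space.
#'
#' @param net a \code{spine_network}
#' @param zap entries with absolute value below \code{zap} (after
#'   normalisation) are set to zero for readability
#' @return list of named weight vectors; empty list if no conservation law
#' @export
conserved_moieties <- function(net, zap = 1e-10) {
  S <- stoichiometry_matrix(net)
  if (ncol(S) == 0L) {
    out <- lapply(seq_len(nrow(S)), function(i) {
      w <- numeric(nrow(S)); names(w) <- rownames(S); w[i] <- 1; w
    })
    return(out)
  }
  sv <- svd(S, nu = nrow(S))
  tolr <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps * 100
  rank <- sum(sv$d > tolr)
  if (rank == nrow(S)) return(list())
  basis <- sv$u[, (rank + 1L):nrow(S), drop = FALSE]
  lapply(seq_len(ncol(basis)), function(j) {
    w <- basis[, j]
    w <- w / max(abs(w))
    w[abs(w) < zap] <- 0
    names(w) <- rownames(S)
    w
  })
}

#' Stoichiometry matrix (species x reactions)
#'
#' @param net a \code{spine_network}
#' @return numeric matrix with species rownames and reaction-id colnames
#' @export
stoichiometry_matrix <- function(net) {
  sp <- net$species$name
  S <- matrix(0, nrow = length(sp), ncol = length(net$reactions),
              dimnames = list(sp, vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoich
    S[names(st), j] <- as.numeric(st)
  }
  S
}

#' Evaluate a conserved amount along a state
#'
#' @param net network
#' @param w weight vector from \code{\link{conserved_moieties}}
#' @param state concentration vector
#' @return scalar conserved amount (uM * um^3, i.e. proportional to molecules)
#' @export
moiety_amount <- function(net, w, state) {
  if (is.null(net$compiled)) net <- compile_network(net)
  y <- as.numeric(state_in_order(net, state))
  sum(w * net$compiled$vol * y)
}

#' Initial state vector of a network
#'
#' @param net network
#' @return named concentration vector, uM
#' @export
initial_state <- function(net) {
  stats::setNames(net$species$initial, net$species$name)
}

#' Integrate a network trajectory
#'
#' Wraps \code{deSolve::lsoda} (or another deSolve method). If
#' \code{restart_at} times are given (typically stimulus event times), the
#' integration is split into segments so the adaptive solver cannot step over
#' sharp forcing transients.
#'
#' @param net a \code{spine_network}
#' @param times strictly increasing output time grid, s
#' @param init initial state; defaults to the declared initial concentrations
#' @param inputs named list of forcing functions of time
#' @param restart_at numeric vector of interior times at which the solver is
#'   restarted (forcing discontinuities)
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-12 uM)
#' @param method deSolve method name
#' @param hmax maximum solver step, passed to deSolve
#' @return matrix: first column \code{time}, then one column per species (uM),
#'   negatives clipped to zero for reporting
#' @export
simulate_network <- function(net, times, init = NULL, inputs = list(),
                             restart_at = numeric(0), rtol = 1e-8,
                             atol = 1e-12, method = "lsoda", hmax = NULL) {
  if (is.null(net$compiled)) net <- compile_network(net)
  if (is.null(init)) init <- initial_state(net)
  y0 <- as.numeric(state_in_order(net, init))
  # inside the integrator, transiently negative trial states are clamped to
  # zero for rate evaluation (adaptive solvers probe such states and reject
  # the step on their own); the hard negativity error applies only to
  # user-supplied states via network_derivative()
  rhs <- network_rhs(net, inputs, neg_tol = Inf)
  sp <- net$species$name

  cuts <- sort(unique(restart_at))
  cuts <- cuts[cuts > times[1] & cuts < times[length(times)]]
  bounds <- c(times[1], cuts, times[length(times)])

  rows <- vector("list", length(bounds) - 1L)
  y <- y0
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    args <- list(y = y, times = seg_times, func = rhs, parms = NULL,
                 rtol = rtol, atol = atol, method = method)
    if (!is.null(hmax)) args$hmax <- hmax
    sol <- suppressWarnings(do.call(deSolve::ode, args))
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure in segment [", t0, ", ", t1,
           "]; last good time ", max(sol[, 1]))
    keep <- sol[, 1] %in% times | (s == length(bounds) - 1L & sol[, 1] == t1)
    rows[[s]] <- sol[keep & (sol[, 1] > t0 | s == 1L), , drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1])
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  colnames(out) <- c("time", sp)
  out[, -1][out[, -1] < 0] <- 0
  out
}

#' @export
print.spine_network <- function(x, ...) {
  cat("<spine_network>\n")
  cat("  compartments:", paste0(x$compartments$name, " (",
      x$compartments$volume, " um^3)", collapse = ", "), "\n")
  cat("  species:     ", nrow(x$species), "\n")
  cat("  reactions:   ", length(x$reactions), "\n")
  invisible(x)
}
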