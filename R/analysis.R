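# Analysis layer: Riemann-sum AUC, Hill (EC50) fitting, mono-exponential
# decay fitting, spine-level dose-response experiments and the
# receptor-contribution decomposition.

#' Above-baseline area under the curve (left-endpoint Riemann sum)
#'
#' @param time uniform time grid, s
#' @param value signal values, uM
#' @param baseline baseline to subtract, uM
#' @param normalise optional reference AUC; if given, the \code{fold} element
#'   is \code{value / normalise}
#' @param grid_tol relative tolerance on grid uniformity
#' @return list with \code{value} (uM s), \code{baseline}, \code{fold}
#' @export
auc_riemann <- function(time, value, baseline = 0, normalise = NULL,
                        grid_tol = 1e-6) {
  stopifnot(length(time) == length(value), length(time) >= 2,
            is.finite(baseline))
  dt <- diff(time)
  if (diff(range(dt)) > grid_tol * mean(dt))
    stop("auc_riemann requires a uniform time grid; resample first")
  v <- value - baseline
  out <- list(value = sum(v[-length(v)]) * mean(dt), baseline = baseline)
  out$fold <- if (!is.null(normalise)) out$value / normalise else NA_real_
  out
}

#' Four-parameter logistic (Hill) fit on log-dose
#'
#' Least-squares fit of \code{bottom + (top - bottom) / (1 + (EC50/d)^n)}.
#' Requires at least four doses spanning the transition.
#'
#' @param dose dose vector (> 0 entries are used; an exact-zero dose is kept
#'   as the bottom anchor)
#' @param response response vector
#' @param fixed_bottom optional fixed bottom asymptote
#' @return object of class \code{hill_fit}: list with \code{ec50}, \code{n},
#'   \code{top}, \code{bottom}, \code{residual}, \code{fitted}
#' @export
fit_hill <- function(dose, response, fixed_bottom = NULL) {
  stopifnot(length(dose) == length(response))
  if (length(dose) < 4) stop("Hill fit is under-determined with < 4 points")
  pos <- dose > 0
  d <- dose[pos]; y <- response[pos]
  if (length(unique(d)) < 4)
    stop("Hill fit needs >= 4 distinct positive doses")
  rng <- range(y)
  if (diff(rng) <= 0) stop("response does not vary across doses")
  # crude span check: responses must approach both asymptotes
  y0 <- if (!is.null(fixed_bottom)) fixed_bottom else min(y)
  half <- (max(y) + y0) / 2
  ec50_0 <- stats::approx(y, d, xout = half, ties = "ordered")$y
  if (!is.finite(ec50_0)) ec50_0 <- exp(mean(log(range(d))))
  start <- list(lec50 = log(ec50_0), n = 1,
                top = max(y))
  lower <- c(lec50 = log(min(d)) - 5, n = 0.2, top = -Inf)
  upper <- c(lec50 = log(max(d)) + 5, n = 8, top = Inf)
  if (is.null(fixed_bottom)) {
    start$bottom <- min(y)
    form <- y ~ bottom + (top - bottom) / (1 + exp(n * (lec50 - log(d))))
    lower <- c(lower, bottom = -Inf); upper <- c(upper, bottom = Inf)
  } else {
    form <- y ~ fixed_bottom + (top - fixed_bottom) /
      (1 + exp(n * (lec50 - log(d))))
  }
  fit <- minpack.lm::nlsLM(form, data = data.frame(d = d, y = y),
                           start = start, lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  res <- list(ec50 = exp(cf[["lec50"]]), n = cf[["n"]], top = cf[["top"]],
              bottom = if (is.null(fixed_bottom)) cf[["bottom"]]
                       else fixed_bottom,
              residual = sqrt(mean(stats::resid(fit)^2)),
              fitted = stats::fitted(fit))
  if (res$bottom > res$top) {
    # decreasing curve: report with asymptotes swapped for the invariant
    # bottom <= top
    tmp <- res$bottom; res$bottom <- res$top; res$top <- tmp
  }
  class(res) <- "hill_fit"
  res
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> EC50 = ", signif(x$ec50, 4), " uM, n = ",
      signif(x$n, 3), ", range [", signif(x$bottom, 4), ", ",
      signif(x$top, 4), "]\n", sep = "")
  invisible(x)
}

#' Mono-exponential decay fit from the post-stimulus peak
#'
#' Fits \code{baseline + A exp(-(t - t_peak)/tau)} by least squares on the
#' segment from the global maximum after \code{from} to the end of the
#' record.
#'
#' @param time time vector, s
#' @param value signal vector, uM
#' @param from only consider peaks at or after this time (default 0; set to
#'   the last stimulus time)
#' @param baseline optional fixed baseline; estimated if NULL
#' @return object of class \code{decay_fit}: \code{tau} (s),
#'   \code{amplitude}, \code{baseline}, \code{t_peak}, \code{residual}
#' @export
fit_mono_exponential_decay <- function(time, value, from = 0,
                                       baseline = NULL) {
  sel <- time >= from
  ip <- which(sel)[which.max(value[sel])]
  tt <- time[ip:length(time)] - time[ip]
  yy <- value[ip:length(time)]
  if (length(tt) < 5) stop("decay segment too short to fit")
  if (yy[length(yy)] >= yy[1])
    stop("segment after the peak does not decay; cannot fit")
  b0 <- if (is.null(baseline)) min(yy) else baseline
  A0 <- max(yy[1] - b0, .Machine$double.eps)
  # crude tau from the 1/e crossing
  cross <- which(yy - b0 <= A0 / exp(1))[1]
  tau0 <- if (is.finite(cross) && !is.na(cross) && cross > 1) tt[cross]
          else max(tt) / 3
  dfit <- data.frame(tt = tt, yy = yy)
  if (is.null(baseline)) {
    fit <- minpack.lm::nlsLM(yy ~ b + A * exp(-tt / tau), data = dfit,
      start = list(b = b0, A = A0, tau = tau0),
      lower = c(b = -Inf, A = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(yy ~ baseline + A * exp(-tt / tau), data = dfit,
      start = list(A = A0, tau = tau0),
      lower = c(A = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  structure(list(tau = cf[["tau"]], amplitude = cf[["A"]],
                 baseline = if (is.null(baseline)) cf[["b"]] else baseline,
                 t_peak = time[ip],
                 residual = sqrt(mean(stats::resid(fit)^2))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> tau = ", signif(x$tau, 4), " s, amplitude = ",
      signif(x$amplitude, 4), ", baseline = ", signif(x$baseline, 4), "\n",
      sep = "")
  invisible(x)
}

#' Spine-level dose-response to square glutamate applications
#'
#' For each concentration, applies a square glutamate pulse (default 1 s)
#' uniformly at the receptor locations of a (typically mGluRI-only) spine
#' model and records the peak of \code{signal} normalised to its baseline;
#' attaches a Hill fit.
#'
#' @param model a \code{spine_model}
#' @param glu_grid concentrations, uM
#' @param signal series column to quantify (\code{"Ca_cyt"} or
#'   \code{"IP3_cyt"})
#' @param pulse_duration square-pulse length, s
#' @param duration simulated time per concentration, s
#' @return \code{dose_response} data.frame with attribute \code{fit}
#' @export
spine_dose_response <- function(model, glu_grid, signal = "Ca_cyt",
                                pulse_duration = 1, duration = 25) {
  glu_grid <- sort(glu_grid)
  base <- model_baseline(model)
  b <- as.numeric(base[signal])
  empty <- release_events(numeric(0))
  resp <- vapply(glu_grid, function(conc) {
    sq <- function(t) ifelse(t >= 0 & t < pulse_duration, conc, 0)
    res <- run_protocol(model, empty, duration = duration, baseline = base,
                        glu_override = sq,
                        extra_restarts = c(0, pulse_duration))
    max(res$series[[signal]]) / b
  }, numeric(1))
  dr <- data.frame(dose = glu_grid, response = resp)
  attr(dr, "fit") <- tryCatch(fit_hill(dr$dose, dr$response),
                              error = function(e) NULL)
  class(dr) <- c("dose_response", class(dr))
  dr
}

#' Receptor-contribution decomposition
#'
#' Runs the same protocol on the mGluRI-only, AMPA/NMDA-only and
#' all-receptor variants of a configuration and tabulates above-baseline
#' AUCs for cytosolic Ca and IP3 plus the additivity index
#' AUC(all) / (AUC(mGluRI) + AUC(iGluR)).
#'
#' @param cfg a \code{\link{spine_config}} (its \code{receptors} entry is
#'   overridden per run)
#' @param protocol a \code{stimulus_protocol}
#' @param duration simulated time, s (default from the protocol)
#' @return list with \code{table} (data.frame subset x signal AUCs) and
#'   \code{additivity} (named vector for Ca and IP3)
#' @export
contribution_decomposition <- function(cfg, protocol, duration = NULL) {
  subsets <- c("mglur", "iglur", "all")
  auc <- sapply(subsets, function(ss) {
    cfg2 <- cfg
    cfg2$simulation$receptors <- ss
    model <- assemble_spine_model(cfg2)
    res <- run_protocol(model, protocol, duration = duration)
    vapply(c("Ca_cyt", "IP3_cyt"), function(sg)
      auc_riemann(res$series$time, res$series[[sg]],
                  baseline = as.numeric(res$baseline[sg]))$value,
      numeric(1))
  })
  additivity <- c(
    Ca = auc["Ca_cyt", "all"] / (auc["Ca_cyt", "mglur"] +
                                   auc["Ca_cyt", "iglur"]),
    IP3 = auc["IP3_cyt", "all"] / (auc["IP3_cyt", "mglur"] +
                                     auc["IP3_cyt", "iglur"]))
  list(table = as.data.frame(t(auc)), additivity = additivity)
}
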