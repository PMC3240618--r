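# Cached whole-model experiments shared between the integration and
# acceptance tests (each is computed once per test session).

spine_model_for <- function(receptors, location, transporters = "on") {
  tag <- paste("model", receptors, location, transporters, sep = "_")
  cached(tag, {
    cfg <- spine_config()
    cfg$simulation$receptors <- receptors
    cfg$simulation$mglur_location <- location
    cfg$simulation$transporters <- transporters
    cfg$simulation$dt <- 0.002
    assemble_spine_model(cfg)
  })
}

spine_run <- function(receptors, location, protocol_tag, transporters = "on") {
  tag <- paste("run", receptors, location, protocol_tag, transporters,
               sep = "_")
  cached(tag, {
    model <- spine_model_for(receptors, location, transporters)
    pr <- switch(protocol_tag,
      single = make_protocol("single"),
      tbs5 = make_protocol("tbs5"),
      tbs9 = make_protocol("tbs9"),
      tet100 = make_protocol("tetanus", frequency = 100, duration = 1))
    run_protocol(model, pr)
  })
}

run_auc <- function(res, signal) {
  auc_riemann(res$series$time, res$series[[signal]],
              baseline = as.numeric(res$baseline[signal]))$value
}

receptor_ec50s <- function() {
  cached("receptor_ec50s", {
    net <- build_cascade_network()
    dr <- galphagtp_dose_response(10^seq(-2, 3, length.out = 12), net = net)
    db <- glutamate_binding_curve(10^seq(-3, 2, length.out = 12))
    list(functional = attr(dr, "fit")$ec50, binding = attr(db, "fit")$ec50)
  })
}

pulse_ec50 <- function(signal) {
  cached(paste0("pulse_ec50_", signal), {
    model <- spine_model_for("mglur", 100)
    model$config$simulation$dt <- 0.002
    dr <- spine_dose_response(model, 10^seq(-1.5, 1.5, length.out = 7),
                              signal, duration = 12)
    attr(dr, "fit")$ec50
  })
}
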