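# Stimulation-protocol library.
#
# All protocols are deterministic lists of glutamate release events (time,
# molecules). A burst is 4 pulses at 100 Hz; theta-burst stimulation (TBS)
# repeats bursts with 200 ms between burst onsets (5 Hz theta rhythm);
# tetanus delivers f pulses per second for a fixed duration.

#' Construct a stimulation protocol
#'
#' @param name one of \code{"single"}, \code{"burst4"}, \code{"tbs5"},
#'   \code{"tbs9"}, \code{"tetanus"}, \code{"pulses"}
#' @param frequency pulse frequency, Hz (\code{tetanus}/\code{pulses})
#' @param duration tetanus duration, s
#' @param n_pulses pulse count (\code{pulses})
#' @param n_bursts burst count for a custom TBS (\code{tbs5}/\code{tbs9}
#'   presets ignore it)
#' @param molecules glutamate molecules per release event
#' @return object of class \code{stimulus_protocol} with an \code{events}
#'   data.frame
#' @export
make_protocol <- function(name, frequency = 100, duration = 1,
                          n_pulses = NULL, n_bursts = NULL,
                          molecules = 3000) {
  name <- match.arg(name, c("single", "burst4", "tbs5", "tbs9", "tetanus",
                            "pulses"))
  if (frequency <= 0) stop("frequency must be > 0 Hz")
  burst <- function(t0) t0 + seq(0, by = 0.01, length.out = 4)
  times <- switch(name,
    single = 0,
    burst4 = burst(0),
    tbs5 = as.vector(vapply(seq(0, by = 0.2, length.out = 5), burst,
                            numeric(4))),
    tbs9 = as.vector(vapply(seq(0, by = 0.2, length.out = 9), burst,
                            numeric(4))),
    tetanus = seq(0, duration - 1 / frequency, by = 1 / frequency),
    pulses = {
      if (is.null(n_pulses)) stop("pulses protocol needs n_pulses")
      seq(0, by = 1 / frequency, length.out = n_pulses)
    })
  if (name %in% c("tbs5", "tbs9") && !is.null(n_bursts))
    times <- as.vector(vapply(seq(0, by = 0.2, length.out = n_bursts),
                              burst, numeric(4)))
  structure(list(name = name, events = release_events(sort(times), molecules)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", x$name, ": ", nrow(x$events), " events over ",
      if (nrow(x$events)) max(x$events$time) else 0, " s\n", sep = "")
  invisible(x)
}
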