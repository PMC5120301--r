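#' A single stimulation event
#'
#' A timed perturbation of the cortical variables PY and IN1. In `"jump"`
#' mode (the default) the perturbation is applied instantaneously in state
#' space: `direction * magnitude` is added to the targeted variables at the
#' first integration grid point at or after `time`. In `"pulse"` mode the
#' same quantity is added to the targeted derivatives over
#' `[time, time + duration)`.
#'
#' @param time event time in seconds (within the simulation window).
#' @param magnitude non-negative amplitude.
#' @param direction sign of the perturbation; the model convention is
#'   negative (hyperpolarising) stimulation.
#' @param mode `"jump"` or `"pulse"`.
#' @param duration pulse length in seconds (pulse mode only; ignored for
#'   jumps).
#' @param targets which cortical variables receive the perturbation;
#'   by default both PY and IN1 at equal magnitude.
#' @return An object of class `swd_event`.
#' @export
stim_event <- function(time, magnitude, direction = -1,
                       mode = c("jump", "pulse"), duration = 0.05,
                       targets = c("PY", "IN1")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time), time >= 0)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0)
    stop("stimulus magnitude must be a non-negative scalar")
  if (!all(targets %in% c("PY", "IN1")))
    stop("stimulus targets must be a subset of c('PY', 'IN1')")
  if (mode == "pulse" && (!is.numeric(duration) || duration <= 0))
    stop("pulse duration must be positive")
  structure(list(time = time, magnitude = magnitude, direction = sign(direction),
                 mode = mode, duration = duration, targets = targets),
            class = "swd_event")
}

#' A stimulation protocol
#'
#' An ordered collection of [stim_event()]s applied during one simulation.
#'
#' @param ... `swd_event` objects (or a single list of them).
#' @return An object of class `swd_protocol` (events sorted by time).
#' @export
stim_protocol <- function(...) {
  ev <- list(...)
  if (length(ev) == 1L && !inherits(ev[[1]], "swd_event")) ev <- ev[[1]]
  if (!all(vapply(ev, inherits, logical(1), "swd_event")))
    stop("all protocol entries must be stim_event objects")
  ev <- ev[order(vapply(ev, `[[`, numeric(1), "time"))]
  structure(list(events = ev), class = "swd_protocol")
}

#' Periodic initiation/termination protocol
#'
#' Expands a periodic double-pulse pattern: an initiation event of
#' magnitude `initiation` at `t0 + n * period` and a termination event of
#' magnitude `termination` at `t0 + offset + n * period`, for
#' `n = 0 .. n_periods - 1`. This is the pattern that drives recurrent
#' seizure onsets and offsets.
#'
#' @param t0 time of the first initiation event (s).
#' @param period repetition period (s).
#' @param initiation,termination magnitudes of the two event types.
#' @param offset delay of each termination event after its initiation (s).
#' @param n_periods number of repetitions.
#' @param ... further arguments passed to [stim_event()] (direction, mode).
#' @return An `swd_protocol`.
#' @export
periodic_protocol <- function(t0 = 20, period = 20, initiation = 0.3,
                              termination = 0.2, offset = 15, n_periods = 2, ...) {
  stopifnot(period > 0, offset > 0, offset < period, n_periods >= 1)
  ev <- list()
  for (n in seq_len(n_periods) - 1L) {
    ev <- c(ev, list(stim_event(t0 + n * period, initiation, ...),
                     stim_event(t0 + offset + n * period, termination, ...)))
  }
  stim_protocol(ev)
}

#' @export
print.swd_protocol <- function(x, ...) {
  cat("Stimulation protocol with", length(x$events), "event(s)\n")
  for (e in x$events)
    cat(sprintf("  t = %g s  %s  magnitude %g (direction %+d) -> %s\n",
                e$time, e$mode, e$magnitude, e$direction,
                paste(e$targets, collapse = ", ")))
  invisible(x)
}

# Events matrix for the compiled integrator:
# columns (time, amp_py, amp_in1, mode, duration), amplitudes signed.
protocol_matrix <- function(protocol, duration) {
  if (is.null(protocol)) return(matrix(numeric(0), 0, 5))
  if (inherits(protocol, "swd_event")) protocol <- stim_protocol(protocol)
  stopifnot(inherits(protocol, "swd_protocol"))
  rows <- lapply(protocol$events, function(e) {
    if (e$time > duration)
      stop("stimulus event at t = ", e$time, " s lies outside the simulation window")
    amp <- e$direction * e$magnitude
    c(e$time,
      if ("PY" %in% e$targets) amp else 0,
      if ("IN1" %in% e$targets) amp else 0,
      if (e$mode == "jump") 0 else 1,
      e$duration)
  })
  do.call(rbind, rows)
}
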