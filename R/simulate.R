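#' Simulation configuration
#'
#' Integration settings for [simulate_field()]. The reference settings are
#' a 1 ms step, 20 s of simulated time, and a 5 s transient that analysis
#' routines discard.
#'
#' @param dt integration step (s), > 0.
#' @param duration simulated time (s).
#' @param transient initial interval excluded from analysis (s), < duration.
#' @param initial_state length-5 initial state; defaults to [default_state()].
#' @param ramp optional [ramp_schedule()] making one parameter time-varying.
#' @return An object of class `swd_config`.
#' @export
sim_config <- function(dt = 0.001, duration = 20, transient = 5,
                       initial_state = default_state(), ramp = NULL) {
  stopifnot(dt > 0, duration > dt, transient >= 0, transient < duration)
  if (!is.null(ramp)) stopifnot(inherits(ramp, "swd_ramp"))
  structure(list(dt = dt, duration = duration, transient = transient,
                 initial_state = as_state(initial_state), ramp = ramp),
            class = "swd_config")
}

#' Linear parameter ramp
#'
#' Declares one model constant as a linear function of time:
#' `value(t) = from` for `t <= t_start`, `to` for `t >= t_end`, linear in
#' between. Used for slow parameter drifts such as a thalamocortical
#' coupling growing over hundreds of seconds.
#'
#' @param param parameter name (e.g. `"k4"`).
#' @param from,to start and end values.
#' @param t_start,t_end ramp window (s), `t_start < t_end`.
#' @return An object of class `swd_ramp`.
#' @export
ramp_schedule <- function(param, from, to, t_start, t_end) {
  stopifnot(t_start < t_end, is.finite(from), is.finite(to))
  param_offset(param) # validates the name
  structure(list(param = param, from = from, to = to,
                 t_start = t_start, t_end = t_end),
            class = "swd_ramp")
}

#' Integrate the thalamocortical field model
#'
#' Fixed-step fourth-order Runge-Kutta integration of the five-population
#' system under an optional stimulation protocol. State-jump events modify
#' the state at the first grid point at or after their event time;
#' rectangular pulses add to the cortical derivatives while active. The
#' integrator is deterministic: repeated calls are bit-identical.
#'
#' @param params an [field_params()] object.
#' @param config an [sim_config()] object.
#' @param protocol an [stim_protocol()], a single [stim_event()], or `NULL`.
#' @return An object of class `swd_trajectory`: list with `time` (s),
#'   `state` (matrix, columns PY, IN1, IN2, TC, RE), `mean` (the cortical
#'   mean `(PY + IN1) / 2`), plus the `dt`, `transient` and `config` used.
#' @examples
#' p <- field_params()
#' tr <- simulate_field(p, sim_config(duration = 2, transient = 1))
#' range(tr$mean)
#' @export
simulate_field <- function(params, config = sim_config(), protocol = NULL) {
  validate_params(params)
  stopifnot(inherits(config, "swd_config"))
  nsteps <- as.integer(round(config$duration / config$dt))
  ev <- protocol_matrix(protocol, config$duration)
  if (is.null(config$ramp)) {
    ridx <- -1L; r0 <- 0; r1 <- 0; v0 <- 0; v1 <- 0
  } else {
    ridx <- param_offset(config$ramp$param)
    r0 <- config$ramp$t_start; r1 <- config$ramp$t_end
    v0 <- config$ramp$from; v1 <- config$ramp$to
  }
  st <- .rk4_field(param_vector(params), config$initial_state, config$dt,
                   nsteps, ev, ridx, r0, r1, v0, v1)
  colnames(st) <- c("PY", "IN1", "IN2", "TC", "RE")
  structure(list(
    time = seq(0, by = config$dt, length.out = nsteps + 1L),
    state = st,
    mean = (st[, 1L] + st[, 2L]) / 2,
    dt = config$dt,
    transient = config$transient,
    config = config
  ), class = "swd_trajectory")
}

#' Cortical-mean observable of a trajectory
#'
#' @param traj an `swd_trajectory`.
#' @param from,to optional time window (s); defaults to the full run.
#' @return Numeric vector of `(PY + IN1) / 2` samples.
#' @export
cortical_mean <- function(traj, from = NULL, to = NULL) {
  stopifnot(inherits(traj, "swd_trajectory"))
  x <- traj$mean
  if (is.null(from) && is.null(to)) return(x)
  if (is.null(from)) from <- 0
  if (is.null(to)) to <- traj$time[length(traj$time)]
  x[traj$time >= from & traj$time <= to]
}

#' @export
print.swd_trajectory <- function(x, ...) {
  cat(sprintf("swd_trajectory: %d samples, dt = %g s, duration = %g s\n",
              length(x$time), x$dt, x$time[length(x$time)]))
  cat(sprintf("  cortical mean range: [%.4g, %.4g]\n",
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
as.data.frame.swd_trajectory <- function(x, ...) {
  data.frame(t = x$time, x$state, mean = x$mean)
}
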