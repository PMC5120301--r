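#' One-parameter state scan
#'
#' Simulates the model over a grid of one coupling strength, classifying
#' the terminal window of each run. Initial conditions are either fixed
#' (`mode = "fixed"`, the reference initial state for every grid value) or
#' inherited from the end state of the previous run, scanning the grid
#' forwards or backwards. Comparing forward and backward inherited scans
#' exposes hysteresis: their labels differ only inside bistable windows.
#'
#' With `stimulus = "pulse"`, each run lasts `stim_duration` seconds and an
#' initiation event (`pulse_magnitude`, negative direction, PY and IN1) is
#' applied at `pulse_time`; the label then reflects the stimulated regime.
#'
#' @param params an [field_params()] object (the swept entry is overridden).
#' @param param name of the swept parameter, e.g. `"k4"`; a character vector
#'   sweeps a group of constants set jointly to each grid value.
#' @param grid strictly monotone numeric grid.
#' @param mode initial-condition policy: `"fixed"`, `"forward"` or
#'   `"backward"` (inherited).
#' @param stimulus `"none"` or `"pulse"`.
#' @param config base [sim_config()] for unstimulated runs.
#' @param pulse_magnitude,pulse_time,stim_duration stimulated-run settings.
#' @param window classification window (s) at the end of each run.
#' @param ... classification options passed to [classify_trajectory()].
#' @return A data frame of class `swd_scan`: one row per grid value with
#'   `value`, `label`, `frequency`, `amplitude`, `maxima_per_cycle`,
#'   `n_maxima`, `n_minima`, `failed`. Integration blow-ups flag the cell
#'   and the scan continues.
#' @export
scan_1d <- function(params, param, grid,
                    mode = c("fixed", "forward", "backward"),
                    stimulus = c("none", "pulse"),
                    config = sim_config(),
                    pulse_magnitude = 0.3, pulse_time = 20,
                    stim_duration = 50, window = 10, ...) {
  mode <- match.arg(mode)
  stimulus <- match.arg(stimulus)
  d <- diff(grid)
  if (length(grid) < 2L || !(all(d > 0) || all(d < 0)))
    stop("grid must be strictly monotone")
  order_idx <- if (mode == "backward") rev(seq_along(grid)) else seq_along(grid)

  proto <- NULL
  if (stimulus == "pulse") {
    proto <- stim_protocol(stim_event(pulse_time, pulse_magnitude))
    config <- sim_config(dt = config$dt, duration = stim_duration,
                         transient = config$transient,
                         initial_state = config$initial_state)
  }

  n <- length(grid)
  out <- data.frame(value = grid, label = NA_character_, frequency = NA_real_,
                    amplitude = NA_real_, maxima_per_cycle = NA_integer_,
                    n_maxima = NA_integer_, n_minima = NA_integer_,
                    failed = FALSE)
  ic <- config$initial_state
  for (i in order_idx) {
    p_i <- set_group(params, param, grid[i])
    cfg <- config
    if (mode != "fixed") cfg$initial_state <- as_state(ic)
    tr <- tryCatch(simulate_field(p_i, cfg, proto), error = function(e) e)
    if (inherits(tr, "error")) {
      out$failed[i] <- TRUE
      next
    }
    if (mode != "fixed") ic <- tr$state[nrow(tr$state), ]
    lab <- classify_trajectory(tr, window = window, ...)
    s <- attr(lab, "summary")
    out$label[i] <- as.character(lab)
    out$frequency[i] <- s$frequency
    out$amplitude[i] <- s$amplitude
    out$maxima_per_cycle[i] <- s$maxima_per_cycle
    out$n_maxima[i] <- length(s$maxima)
    out$n_minima[i] <- length(s$minima)
  }
  structure(out, param = param, mode = mode, stimulus = stimulus,
            class = c("swd_scan", "data.frame"))
}

#' Two-parameter state map
#'
#' For every cell of a two-parameter grid, runs the model without
#' stimulation (base label) and, when `pulsed = TRUE`, again with a single
#' initiation event; cells whose background state (SATURATED_LOW) converts
#' to SWD under the pulse are labelled `STIMULUS_INDUCED_SWD`, cells that
#' show SWD without any stimulus `SPONTANEOUS_SWD`, all others keep their
#' base label.
#'
#' @param params base parameter set.
#' @param names the two swept parameter names; either a character vector of
#'   length 2 or a list of two character vectors, each vector naming a group
#'   of constants set to the same value (e.g. `list(c("k3", "k6"), "k4")`
#'   to sweep the joint output strength of the slow interneuron population).
#' @param grid_x,grid_y numeric grids for `names[1]` and `names[2]`.
#' @param pulsed whether to run the paired stimulated simulation.
#' @param config,pulse_magnitude,pulse_time,stim_duration,window,... as in
#'   [scan_1d()].
#' @return Data frame of class `swd_map`: one row per cell with the two
#'   parameter values, `base_label`, `pulsed_label` (NA if `pulsed = FALSE`)
#'   and the derived `label`.
#' @export
state_map_2d <- function(params, names, grid_x, grid_y, pulsed = TRUE,
                         config = sim_config(), pulse_magnitude = 0.3,
                         pulse_time = 20, stim_duration = 50, window = 10, ...) {
  nm <- if (is.list(names)) names else as.list(names)
  stopifnot(length(nm) == 2L, all(vapply(nm, is.character, logical(1))))
  cells <- expand.grid(x = grid_x, y = grid_y, KEEP.OUT.ATTRS = FALSE)
  base <- pulse <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p_i <- set_group(set_group(params, nm[[1]], cells$x[i]), nm[[2]], cells$y[i])
    tr0 <- tryCatch(simulate_field(p_i, config), error = function(e) e)
    base[i] <- if (inherits(tr0, "error")) "FAILED"
      else as.character(classify_trajectory(tr0, window = window, ...))
    if (pulsed) {
      cfgs <- sim_config(dt = config$dt, duration = stim_duration,
                         transient = config$transient,
                         initial_state = config$initial_state)
      tr1 <- tryCatch(
        simulate_field(p_i, cfgs, stim_event(pulse_time, pulse_magnitude)),
        error = function(e) e)
      pulse[i] <- if (inherits(tr1, "error")) "FAILED"
        else as.character(classify_trajectory(tr1, window = window, ...))
    } else pulse[i] <- NA_character_
  }
  label <- base
  label[base == "SWD"] <- "SPONTANEOUS_SWD"
  if (pulsed)
    label[base == "SATURATED_LOW" & pulse == "SWD"] <- "STIMULUS_INDUCED_SWD"
  out <- data.frame(cells$x, cells$y, base_label = base,
                    pulsed_label = pulse, label = label)
  names(out)[1:2] <- vapply(nm, paste, character(1), collapse = ".")
  structure(out, class = c("swd_map", "data.frame"))
}

#' Outcome of a double-pulse initiation/termination experiment
#'
#' Runs one simulation with an initiation event of magnitude `I` at `t_I`
#' and a termination event of magnitude `T_amp` at `t_T`, then classifies
#' the window before the termination event and the final window:
#' \describe{
#'   \item{A}{neither stimulation produces SWD;}
#'   \item{B}{the first fails but the second initiates SWD;}
#'   \item{C}{SWD is initiated and survives the second stimulation;}
#'   \item{D}{SWD is initiated and the second stimulation abates it.}
#' }
#'
#' @param params parameter set.
#' @param I,T_amp initiation and termination magnitudes.
#' @param t_I,t_T event times (s), `t_I < t_T`.
#' @param duration total simulated time (s).
#' @param window classification window (s): the last `window` seconds
#'   before `t_T` and the last `window` seconds of the run (kept clear of
#'   the several-second excitable transients that follow each pulse).
#' @param config base configuration (dt, initial state).
#' @param ... classification options.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, with attribute `"labels"`
#'   giving the two window labels.
#' @export
double_pulse_outcome <- function(params, I, T_amp, t_I = 20, t_T = 35,
                                 duration = 50, window = 10,
                                 config = sim_config(), ...) {
  if (t_I >= t_T || t_T >= duration) stop("need t_I < t_T < duration")
  if (t_T - t_I < window || duration - t_T < window)
    stop("windows overlap the stimulation events")
  proto <- stim_protocol(stim_event(t_I, I), stim_event(t_T, T_amp))
  cfg <- sim_config(dt = config$dt, duration = duration,
                    transient = config$transient,
                    initial_state = config$initial_state)
  tr <- simulate_field(params, cfg, proto)
  w1 <- classify_state(cortical_mean(tr, from = t_T - window, to = t_T),
                       tr$dt, ...)
  w2 <- classify_state(cortical_mean(tr, from = duration - window), tr$dt, ...)
  swd1 <- as.character(w1) == "SWD"
  swd2 <- as.character(w2) == "SWD"
  out <- if (!swd1 && !swd2) "A" else if (!swd1 && swd2) "B"
    else if (swd1 && swd2) "C" else "D"
  structure(out, labels = c(before = as.character(w1), after = as.character(w2)))
}

#' Map of double-pulse outcomes over the (I, T) plane
#'
#' @param params parameter set.
#' @param I_grid,T_grid magnitude grids for the initiation and termination
#'   events.
#' @param ... passed to [double_pulse_outcome()].
#' @return Data frame with columns `I`, `T_amp`, `region`.
#' @export
pulse_plane_map <- function(params, I_grid = seq(0, 0.5, by = 0.01),
                            T_grid = seq(0, 0.5, by = 0.01), ...) {
  cells <- expand.grid(I = I_grid, T_amp = T_grid, KEEP.OUT.ATTRS = FALSE)
  cells$region <- vapply(seq_len(nrow(cells)), function(i)
    as.character(double_pulse_outcome(params, cells$I[i], cells$T_amp[i], ...)),
    character(1))
  cells
}

#' Bisection search for an outcome threshold
#'
#' Refines the smallest magnitude for which `predicate` succeeds, assuming
#' success is (approximately) monotone over the range. The bracket is
#' verified first: if the predicate already succeeds at `lower` that
#' degenerate bracket returns `lower`; if it fails at `upper` the search
#' stops with an error reporting both endpoint outcomes.
#'
#' @param predicate function of one magnitude returning `TRUE`/`FALSE`.
#' @param lower,upper search range.
#' @param resolution final bracket width.
#' @return List: `threshold` (smallest succeeding magnitude on the
#'   bisection grid), `bracket` (the final failing/succeeding pair).
#' @export
threshold_search <- function(predicate, lower, upper, resolution = 0.005) {
  stopifnot(lower < upper, resolution > 0)
  if (isTRUE(predicate(lower)))
    return(list(threshold = lower, bracket = c(lower, lower)))
  if (!isTRUE(predicate(upper)))
    stop("no bracket: predicate is FALSE at ", lower, " and at ", upper)
  lo <- lower; hi <- upper
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (isTRUE(predicate(mid))) hi <- mid else lo <- mid
  }
  list(threshold = hi, bracket = c(lo, hi))
}

#' Simulation under a slow parameter ramp
#'
#' One long run with a linearly ramped parameter, classified in sliding
#' windows; label changes mark the transition timings between firing
#' regimes.
#'
#' @param params parameter set.
#' @param param ramped parameter name.
#' @param from,to ramp endpoint values.
#' @param duration run length (s); the ramp spans the whole run.
#' @param window,step sliding classification window and step (s).
#' @param protocol optional stimulation protocol applied during the ramp.
#' @param dt integration step (s).
#' @param ... classification options.
#' @return List of class `swd_ramp_result`: `trajectory`, `labels`
#'   (data frame `t_mid`, `label` per window) and `transitions`
#'   (data frame `time`, `from`, `to`), timings sorted.
#' @export
ramp_simulation <- function(params, param, from, to, duration = 200,
                            window = 5, step = 1, protocol = NULL,
                            dt = 0.001, ...) {
  cfg <- sim_config(dt = dt, duration = duration, transient = 0,
                    ramp = ramp_schedule(param, from, to, 0, duration))
  tr <- simulate_field(params, cfg, protocol)
  starts <- seq(0, duration - window, by = step)
  labs <- vapply(starts, function(t0) {
    as.character(classify_state(cortical_mean(tr, from = t0, to = t0 + window),
                                dt, ...))
  }, character(1))
  t_mid <- starts + window / 2
  ch <- which(labs[-1L] != labs[-length(labs)])
  transitions <- data.frame(
    time = starts[ch + 1L] + window / 2,
    from = labs[ch], to = labs[ch + 1L])
  structure(list(trajectory = tr,
                 labels = data.frame(t_mid = t_mid, label = labs),
                 transitions = transitions),
            class = "swd_ramp_result")
}
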