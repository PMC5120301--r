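#' Stable local extrema of a time series
#'
#' Local maxima and minima of the post-transient window, by three-point
#' comparison. Plateaus (runs of equal samples between opposite slopes)
#' collapse to a single extremum. A constant series has no extrema.
#'
#' @param series numeric samples (typically a cortical-mean series).
#' @param dt sample interval (s).
#' @param transient leading interval to discard (s).
#' @return List with numeric vectors `maxima` and `minima` (values).
#' @export
stable_extrema <- function(series, dt = 0.001, transient = 0) {
  stopifnot(is.numeric(series), dt > 0, transient >= 0)
  if (length(series) * dt <= transient)
    stop("series shorter than the transient to discard")
  w <- series[seq.int(floor(transient / dt) + 1L, length(series))]
  if (length(w) < 3L) return(list(maxima = numeric(0), minima = numeric(0)))
  d <- sign(diff(w))
  nz <- d != 0
  if (!any(nz)) return(list(maxima = numeric(0), minima = numeric(0)))
  idx <- which(nz)            # slope segments, plateaus dropped
  s <- d[idx]
  turn <- diff(s)             # -2 at a maximum, +2 at a minimum
  at <- idx[-1L][turn != 0]   # sample index just after the turning slope starts
  list(maxima = w[at[turn[turn != 0] < 0]],
       minima = w[at[turn[turn != 0] > 0]])
}

#' Dominant frequency of a time series
#'
#' Frequency of the maximum of the FFT periodogram (mean-subtracted,
#' untapered) over `(0, Nyquist]`. A spectrally flat series below the power
#' floor returns 0 rather than a spurious peak.
#'
#' @param series numeric samples (post-transient window).
#' @param dt sample interval (s).
#' @param power_floor series with standard deviation below this are
#'   reported as steady (frequency 0).
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(series, dt = 0.001, power_floor = 1e-6) {
  stopifnot(is.numeric(series), dt > 0)
  n <- length(series)
  if (n * dt < 1) stop("dominant_frequency: window shorter than 1 s")
  if (stats::sd(series) < power_floor) return(0)
  z <- series - mean(series)
  pow <- Mod(stats::fft(z))^2
  i <- seq(2L, floor(n / 2) + 1L)     # exclude DC, keep up to Nyquist
  freqs <- (i - 1L) / (n * dt)
  freqs[which.max(pow[i])]
}

#' Oscillation summary of a series
#'
#' Extrema, peak-to-peak amplitude, dominant frequency and the number of
#' local maxima per dominant period. The last of these separates spike-wave
#' discharges (a sharp spike plus a slow wave, at least two maxima per
#' cycle) from simple slow-wave oscillations (one maximum per cycle).
#' Maxima values are additionally clustered (gap tolerance 5% of the
#' amplitude) to report the number of distinct maxima levels.
#'
#' @inheritParams stable_extrema
#' @return List: `maxima`, `minima`, `amplitude`, `frequency`,
#'   `maxima_per_cycle` (integer, 0 when steady), `maxima_clusters`.
#' @export
oscillation_summary <- function(series, dt = 0.001, transient = 0) {
  ex <- stable_extrema(series, dt, transient)
  w <- series[seq.int(floor(transient / dt) + 1L, length(series))]
  amp <- if (length(ex$maxima) && length(ex$minima))
    max(ex$maxima) - min(ex$minima) else diff(range(w))
  f <- dominant_frequency(w, dt)
  secs <- length(w) * dt
  mpc <- if (f > 0 && length(ex$maxima)) {
    as.integer(round(length(ex$maxima) / (secs * f)))
  } else 0L
  ncl <- if (length(ex$maxima)) {
    v <- sort(ex$maxima)
    if (amp > 0) sum(diff(v) > 0.05 * amp) + 1L else 1L
  } else 0L
  list(maxima = ex$maxima, minima = ex$minima, amplitude = amp,
       frequency = f, maxima_per_cycle = mpc, maxima_clusters = ncl)
}

#' Classify the firing state of a series
#'
#' Discrete label for the stationary regime of a cortical-mean window:
#' \describe{
#'   \item{SATURATED_LOW / SATURATED_HIGH}{peak-to-peak amplitude below
#'     `amp_tol`; split by the mean level against `level_threshold`.}
#'   \item{TONIC}{oscillatory with dominant frequency `>= tonic_freq_min`
#'     (the high-frequency, low-amplitude regime, ~15 Hz).}
#'   \item{SWD}{dominant frequency inside `swd_band` with at least two
#'     maxima per cycle (spike plus wave).}
#'   \item{CLONIC}{dominant frequency inside `swd_band` with one maximum
#'     per cycle (simple slow wave).}
#'   \item{UNCLASSIFIED}{oscillatory but outside every rule (e.g. slower
#'     than 1 Hz); diagnostics are attached, never a silent guess.}
#' }
#'
#' @param series numeric samples of the analysis window (pass the last,
#'   stationary part of a run; see `window` in [classify_trajectory()]).
#' @param dt sample interval (s).
#' @param amp_tol amplitude below which the series counts as steady.
#' @param level_threshold cortical-mean level splitting low from high
#'   saturation (the two branches sit near 0.17 and 0.5).
#' @param tonic_freq_min minimum tonic frequency (Hz).
#' @param swd_band frequency band (Hz) of spike-wave and clonic rhythms.
#' @return Character label with attribute `"summary"` (the
#'   [oscillation_summary()] of the window).
#' @export
classify_state <- function(series, dt = 0.001, amp_tol = 1e-3,
                           level_threshold = 0.3, tonic_freq_min = 10,
                           swd_band = c(1, 5)) {
  s <- oscillation_summary(series, dt)
  label <- if (s$amplitude < amp_tol) {
    if (mean(series) < level_threshold) "SATURATED_LOW" else "SATURATED_HIGH"
  } else if (s$frequency >= tonic_freq_min) {
    "TONIC"
  } else if (s$frequency >= swd_band[1] && s$frequency <= swd_band[2]) {
    if (s$maxima_per_cycle >= 2) "SWD" else "CLONIC"
  } else {
    "UNCLASSIFIED"
  }
  structure(label, summary = s)
}

#' Classify the terminal regime of a trajectory
#'
#' Applies [classify_state()] to the last `window` seconds of the cortical
#' mean of a simulated trajectory.
#'
#' @param traj an `swd_trajectory`.
#' @param window analysis window length (s), taken from the end of the run.
#' @param ... passed to [classify_state()].
#' @return Character label (see [classify_state()]).
#' @export
classify_trajectory <- function(traj, window = 10, ...) {
  stopifnot(inherits(traj, "swd_trajectory"))
  t_end <- traj$time[length(traj$time)]
  classify_state(cortical_mean(traj, from = t_end - window), traj$dt, ...)
}
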