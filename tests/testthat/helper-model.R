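# Shared fixtures: reference parameters and a few canonical simulations,
# built once per test run.

ref_params <- field_params()   # (k4, k10) = (1, 3)

# Cortical mean over a time window of a trajectory simulated with a single
# initiation event (the canonical seizure-induction protocol).
swd_trajectory_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- simulate_field(ref_params, sim_config(duration = 50),
                              stim_event(20, 0.3))
    memo
  }
})

# Synthetic spike-wave waveform: 3 Hz fundamental plus harmonics shaping a
# sharp spike on a slow wave (two local maxima per cycle).
synthetic_swd <- function(f0 = 3, dt = 1e-3, secs = 15) {
  t <- seq(0, secs - dt, by = dt)
  0.5 * sin(2 * pi * f0 * t) + 0.35 * sin(2 * pi * 2 * f0 * t + 0.7) +
    0.15 * sin(2 * pi * 3 * f0 * t + 0.3)
}
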