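test_that("integrator shows fourth-order convergence on a smooth window", {
  p <- set_params(ref_params, k4 = 0.4)   # sustained smooth oscillation
  run <- function(dt) {
    tr <- simulate_field(p, sim_config(dt = dt, duration = 2, transient = 0))
    tr$state[nrow(tr$state), ]
  }
  ref <- run(0.000125)
  e1 <- max(abs(run(0.001) - ref))
  e2 <- max(abs(run(0.0005) - ref))
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 32)
})

test_that("a trajectory started at an equilibrium stays there", {
  eq <- find_equilibrium(ref_params)
  tr <- simulate_field(ref_params, sim_config(duration = 20, initial_state = eq))
  expect_lt(max(abs(sweep(tr$state, 2, eq))), 1e-8)
})

test_that("integrator agrees with an independent RK4 implementation", {
  skip_if_not_installed("deSolve")
  p <- ref_params
  y0 <- default_state()
  rhs_desolve <- function(t, y, parms) list(unname(field_rhs(y, p)))
  ref <- deSolve::rk4(unname(y0), seq(0, 1, by = 0.001), rhs_desolve, NULL)
  tr <- simulate_field(p, sim_config(duration = 1, transient = 0))
  expect_equal(unname(tr$state[nrow(tr$state), ]),
               unname(ref[nrow(ref), 2:6]), tolerance = 1e-10)
})

test_that("zero-magnitude events leave the trajectory bit-identical", {
  cfg <- sim_config(duration = 3, transient = 0)
  plain <- simulate_field(ref_params, cfg)
  null_ev <- simulate_field(ref_params, cfg,
                            stim_protocol(stim_event(1, 0), stim_event(2, 0)))
  expect_identical(plain$state, null_ev$state)
})

test_that("state jumps apply the signed magnitude at the first grid point", {
  cfg <- sim_config(duration = 1, transient = 0)
  plain <- simulate_field(ref_params, cfg)
  jumped <- simulate_field(ref_params, cfg, stim_event(0.5, 0.3))
  i <- which(plain$time >= 0.5)[1]
  expect_identical(jumped$state[seq_len(i - 1L), ], plain$state[seq_len(i - 1L), ])
  expect_equal(unname(jumped$state[i, 1:2] - plain$state[i, 1:2]),
               c(-0.3, -0.3), tolerance = 1e-15)
})

test_that("pulse mode perturbs the derivative only while active", {
  cfg <- sim_config(duration = 1, transient = 0)
  plain <- simulate_field(ref_params, cfg)
  pulsed <- simulate_field(ref_params, cfg,
                           stim_event(0.4, 0.5, mode = "pulse", duration = 0.1))
  before <- plain$time < 0.4
  expect_identical(pulsed$state[before, ], plain$state[before, ])
  expect_false(identical(pulsed$state[!before, ], plain$state[!before, ]))
})

test_that("cortical mean is (PY + IN1) / 2 to machine precision", {
  tr <- swd_trajectory_fixture()
  expect_identical(tr$mean, (tr$state[, "PY"] + tr$state[, "IN1"]) / 2)
  expect_equal(length(tr$time), nrow(tr$state))
})

test_that("a constant ramp schedule reproduces the fixed-parameter run exactly", {
  cfg_fix <- sim_config(duration = 5, transient = 0)
  fix <- simulate_field(ref_params, cfg_fix)
  cfg_ramp <- sim_config(duration = 5, transient = 0,
                         ramp = ramp_schedule("k4", 1, 1, 0, 5))
  ramp <- simulate_field(ref_params, cfg_ramp)
  expect_identical(fix$state, ramp$state)
})

test_that("diverging parameter sets raise a step-labelled error", {
  bad <- set_params(ref_params, tau1 = 1e5)   # step size far beyond stability
  expect_error(simulate_field(bad, sim_config(duration = 1, transient = 0)),
               "non-finite state at step")
})

test_that("events outside the window and malformed stimuli are rejected", {
  expect_error(simulate_field(ref_params, sim_config(duration = 1, transient = 0),
                              stim_event(5, 0.3)), "outside")
  expect_error(stim_event(1, -0.2), "non-negative")
  expect_error(stim_event(1, 0.2, targets = "TC"), "targets")
})

test_that("periodic protocols expand to the alternating event pattern", {
  pr <- periodic_protocol(t0 = 20, period = 20, initiation = 0.3,
                          termination = 0.2, offset = 15, n_periods = 3)
  times <- vapply(pr$events, `[[`, numeric(1), "time")
  mags <- vapply(pr$events, `[[`, numeric(1), "magnitude")
  expect_equal(times, c(20, 35, 40, 55, 60, 75))
  expect_equal(mags, rep(c(0.3, 0.2), 3))
})
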