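test_that("stable extrema handle constants, sinusoids and plateaus", {
  expect_equal(stable_extrema(rep(1, 1000)),
               list(maxima = numeric(0), minima = numeric(0)))
  t <- seq(0, 15 - 1e-3, by = 1e-3)
  ex <- stable_extrema(sin(2 * pi * 3 * t), dt = 1e-3)
  expect_equal(length(ex$maxima), 45, tolerance = 0.05)
  expect_equal(length(ex$minima), 45, tolerance = 0.05)
  expect_true(all(abs(ex$maxima - 1) < 1e-4))
  expect_true(all(abs(ex$minima + 1) < 1e-4))
  # plateau at the top collapses to one maximum
  plateau <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, 1, 2)
  ex2 <- stable_extrema(plateau, dt = 1)
  expect_equal(ex2$maxima, 3)
  expect_equal(ex2$minima, 0)
  # transient discard drops leading samples
  ex3 <- stable_extrema(c(rep(5, 1000), sin(2 * pi * 3 * t)), dt = 1e-3,
                        transient = 1)
  expect_equal(length(ex3$maxima), length(ex$maxima), tolerance = 0.1)
  expect_error(stable_extrema(1:10, dt = 1e-3, transient = 1), "shorter")
})

test_that("dominant frequency finds single tones and SWD fundamentals", {
  t <- seq(0, 15 - 1e-3, by = 1e-3)
  expect_equal(dominant_frequency(sin(2 * pi * 3 * t), 1e-3), 3, tolerance = 0.07)
  expect_equal(dominant_frequency(sin(2 * pi * 15 * t), 1e-3), 15, tolerance = 0.07)
  expect_equal(dominant_frequency(rep(0.2, 5000), 1e-3), 0)
  expect_error(dominant_frequency(sin(seq_len(500)), 1e-3), "shorter than 1 s")
  # spike-wave shaped signal: harmonics must not displace the fundamental
  expect_equal(dominant_frequency(synthetic_swd(), 1e-3), 3, tolerance = 0.07)
})

test_that("oscillation summary counts maxima per cycle", {
  s <- oscillation_summary(synthetic_swd(), dt = 1e-3)
  expect_equal(s$frequency, 3, tolerance = 0.07)
  expect_gte(s$maxima_per_cycle, 2)
  t <- seq(0, 15 - 1e-3, by = 1e-3)
  s1 <- oscillation_summary(sin(2 * pi * 3 * t), dt = 1e-3)
  expect_equal(s1$maxima_per_cycle, 1L)
  expect_equal(s1$amplitude, 2, tolerance = 1e-3)
})

test_that("classifier assigns the five base labels and never guesses", {
  t <- seq(0, 15 - 1e-3, by = 1e-3)
  expect_equal(as.character(classify_state(0.15 + 0 * t)), "SATURATED_LOW")
  expect_equal(as.character(classify_state(0.49 + 0 * t)), "SATURATED_HIGH")
  expect_equal(as.character(classify_state(0.2 + 0.05 * sin(2 * pi * 15 * t))),
               "TONIC")
  expect_equal(as.character(classify_state(0.3 + 0.25 * synthetic_swd())), "SWD")
  expect_equal(as.character(classify_state(0.3 + 0.25 * sin(2 * pi * 3 * t))),
               "CLONIC")
  expect_equal(as.character(classify_state(0.3 + 0.2 * sin(2 * pi * 0.5 * t))),
               "UNCLASSIFIED")
  # level threshold is the only route by which an offset changes the label
  expect_equal(as.character(classify_state(0.15 + 0 * t, level_threshold = 0.1)),
               "SATURATED_HIGH")
})

test_that("simulated regimes classify as reported", {
  # background resting state at the reference couplings
  expect_equal(as.character(classify_trajectory(simulate_field(ref_params))),
               "SATURATED_LOW")
  # stimulated run switches to SWD
  expect_equal(as.character(classify_trajectory(swd_trajectory_fixture())),
               "SWD")
  # strong fast-interneuron disinhibition yields tonic oscillation
  p_tonic <- set_params(ref_params, k3 = 1.5, k6 = 1.5, k2 = 1.7, k8 = 1.7)
  expect_equal(as.character(classify_trajectory(simulate_field(p_tonic))),
               "TONIC")
})
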