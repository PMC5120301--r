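test_that("sigmoid activation is a proper firing-rate function", {
  expect_equal(sigmoid_activation(0), 0.5)
  expect_equal(sigmoid_activation(50), 1)        # saturation
  expect_equal(sigmoid_activation(-50), 0)
  # independent log-domain evaluation of 1 / (1 + nu^(-x))
  expect_equal(sigmoid_activation(0.1, 2.5e5),
               exp(-log1p(exp(-0.1 * log(2.5e5)))),
               tolerance = 1e-12)
  expect_equal(round(sigmoid_activation(0.1, 2.5e5), 4), 0.7761)
  x <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(sigmoid_activation(x)) > 0))
  expect_true(all(sigmoid_activation(x) > 0 & sigmoid_activation(x) < 1))
  expect_error(sigmoid_activation(NaN), "non-finite")
  expect_error(sigmoid_activation(0, nu = 1), "nu")
})

test_that("linear activation is exact", {
  expect_identical(linear_activation(0), 0.5)
  expect_identical(linear_activation(1, 2.8, 0.5), 3.3)
  expect_identical(linear_activation(-0.0818), 2.8 * (-0.0818) + 0.5)
})

test_that("parameter constructor carries the reference constants and validates", {
  p <- field_params()
  expect_equal(unname(p$eps), c(-0.35, -3.4, -4.4, -2.0, -5))
  expect_equal(unname(p$tau), c(26, 32.5, 0.13, 2.6, 2.6))
  expect_equal(unname(p$k),
               c(1.8, 1.5, 0.03, 1, 4, 0.03, 3, 1.5, 0.6, 3, 0.2, 10.5, 3))
  expect_equal(p$nu, 2.5e5)
  p2 <- set_params(p, k4 = 1.5)
  expect_equal(unname(p2$k[4]), 1.5)
  expect_equal(p2$k[-4], p$k[-4])       # override isolation
  expect_error(set_params(p, k14 = 1), "unknown")
  expect_error(set_params(p, k4 = -1), "non-negative")
  expect_error(set_params(p, tau3 = 0), "positive")
})

test_that("RHS reduces to decoupled linear decay when all couplings vanish", {
  p0 <- do.call(set_params,
                c(list(field_params()),
                  as.list(setNames(rep(0, 13), paste0("k", 1:13)))))
  y <- c(0.3, -0.2, 0.1, 0.05, -0.4)
  d <- field_rhs(y, p0)
  expect_equal(unname(d), unname(p0$tau * (p0$eps - y)), tolerance = 1e-14)
})

test_that("RHS matches an independently hand-coded scalar implementation", {
  p <- ref_params
  y <- default_state()
  f <- function(x) 1 / (1 + p$nu^(-x))
  s <- function(x) p$alpha * x + p$beta
  k <- unname(p$k); e <- unname(p$eps); tau <- unname(p$tau)
  expected <- c(
    tau[1] * (e[1] - y[1] + k[1] * f(y[1]) - k[2] * f(y[2]) - k[3] * f(y[3]) + k[4] * f(y[4])),
    tau[2] * (e[2] - y[2] + k[5] * f(y[1]) - k[6] * f(y[3])),
    tau[3] * (e[3] - y[3] + k[7] * f(y[1]) - k[8] * f(y[2])),
    tau[4] * (e[4] - y[4] - k[9] * s(y[5]) + k[10] * f(y[1])),
    tau[5] * (e[5] - y[5] - k[11] * s(y[5]) + k[12] * s(y[4]) + k[13] * f(y[1]))
  )
  expect_equal(unname(field_rhs(y, p)), unname(expected), tolerance = 1e-15)
})

test_that("RHS vanishes at a numerically located equilibrium", {
  eq <- find_equilibrium(ref_params)
  expect_lt(max(abs(field_rhs(eq, ref_params))), 1e-10)
})
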