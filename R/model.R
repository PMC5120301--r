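#' Sigmoid firing-rate activation
#'
#' `f(x) = 1 / (1 + nu^(-x))`, the steep sigmoid converting population
#' activity into a normalised firing rate in (0, 1). Evaluated in the log
#' domain for numerical stability at large `|x|`.
#'
#' @param x activity value(s); must be finite.
#' @param nu steepness, > 1.
#' @return Firing rate(s) in (0, 1), strictly increasing in `x`.
#' @examples
#' sigmoid_activation(0)        # 0.5
#' sigmoid_activation(0.1)      # ~0.77 at the default steepness
#' @export
sigmoid_activation <- function(x, nu = 2.5e5) {
  if (any(!is.finite(x))) stop("sigmoid_activation: non-finite input")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 1) stop("nu must be a scalar > 1")
  1 / (1 + exp(-x * log(nu)))
}

#' Linear activation for the thalamic populations
#'
#' `s(x) = alpha * x + beta`, the linearised transfer used for TC and RE.
#'
#' @param x activity value(s).
#' @param alpha slope.
#' @param beta offset.
#' @return `alpha * x + beta`, exactly.
#' @export
linear_activation <- function(x, alpha = 2.8, beta = 0.5) {
  alpha * x + beta
}

#' Right-hand side of the thalamocortical field model
#'
#' Time derivatives of the five population activities. The cortical
#' pyramidal population PY receives recurrent excitation (`k1`), fast and
#' slow cortical inhibition (`k2`, `k3`) and thalamic drive (`k4`); the two
#' interneuron populations IN1 and IN2 mutually inhibit (`k6`, `k8`) and are
#' driven by PY (`k5`, `k7`); the thalamic relay TC and reticular RE
#' populations interact through linearised activations (`k9`..`k13`). Each
#' equation is multiplied by its time-scale factor `tau`, so the small
#' `tau3` makes IN2 the slow (GABA-B like) population.
#'
#' This pure-R evaluation is the reference implementation; [simulate_field()]
#' integrates an equivalent compiled version of the same equations.
#'
#' @param state numeric length-5 state (PY, IN1, IN2, TC, RE).
#' @param params an [field_params()] object.
#' @return Named numeric length-5 derivative.
#' @export
field_rhs <- function(state, params) {
  y <- as_state(state)
  validate_params(params)
  f <- function(x) sigmoid_activation(x, params$nu)
  s <- function(x) linear_activation(x, params$alpha, params$beta)
  eps <- params$eps; tau <- params$tau; k <- params$k
  d <- c(
    PY  = tau[[1]] * (eps[[1]] - y[[1]] + k[[1]] * f(y[[1]]) - k[[2]] * f(y[[2]]) -
                        k[[3]] * f(y[[3]]) + k[[4]] * f(y[[4]])),
    IN1 = tau[[2]] * (eps[[2]] - y[[2]] + k[[5]] * f(y[[1]]) - k[[6]] * f(y[[3]])),
    IN2 = tau[[3]] * (eps[[3]] - y[[3]] + k[[7]] * f(y[[1]]) - k[[8]] * f(y[[2]])),
    TC  = tau[[4]] * (eps[[4]] - y[[4]] - k[[9]] * s(y[[5]]) + k[[10]] * f(y[[1]])),
    RE  = tau[[5]] * (eps[[5]] - y[[5]] - k[[11]] * s(y[[5]]) + k[[12]] * s(y[[4]]) +
                        k[[13]] * f(y[[1]]))
  )
  d
}
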