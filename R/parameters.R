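#' Model parameters for the thalamocortical field model
#'
#' Constructs the full constant set of the five-population ODE system:
#' additive input constants `eps1..eps5`, time-scale multipliers
#' `tau1..tau5`, coupling strengths `k1..k13`, the sigmoid steepness `nu`
#' and the slope/offset `alpha`, `beta` of the linearised thalamic
#' activation. Defaults are the published reference values for the model;
#' individual constants can be overridden by name.
#'
#' The couplings follow the circuit wiring: `k1` PY->PY, `k2` IN1->PY,
#' `k3` IN2->PY, `k4` TC->PY, `k5` PY->IN1, `k6` IN2->IN1, `k7` PY->IN2,
#' `k8` IN1->IN2, `k9` RE->TC, `k10` PY->TC, `k11` RE->RE, `k12` TC->RE,
#' `k13` PY->RE. IN1, IN2 and RE act inhibitorily (negative sign in the
#' equations), PY and TC excitatorily.
#'
#' @param ... named scalar overrides, e.g. `k4 = 1.2`, `tau3 = 0.2`,
#'   `eps1 = -0.3`, `nu = 1e5`.
#' @return An object of class `swd_params`: a list with elements `eps`
#'   (length 5), `tau` (length 5), `k` (length 13), `nu`, `alpha`, `beta`.
#' @examples
#' p <- field_params(k4 = 1, k10 = 3)
#' p$k[4]
#' @export
field_params <- function(...) {
  p <- list(
    eps   = c(-0.35, -3.4, -4.4, -2.0, -5),
    tau   = c(26, 26 * 1.25, 26 * 0.005, 26 * 0.1, 26 * 0.1),
    k     = c(1.8, 1.5, 0.03, 1, 4, 0.03, 3, 1.5, 0.6, 3, 0.2, 10.5, 3),
    nu    = 2.5e5,
    alpha = 2.8,
    beta  = 0.5
  )
  names(p$eps) <- paste0("eps", 1:5)
  names(p$tau) <- paste0("tau", 1:5)
  names(p$k)   <- paste0("k", 1:13)
  class(p) <- "swd_params"
  set_params(p, ...)
}

#' Override individual model constants
#'
#' @param params an `swd_params` object.
#' @param ... named scalar overrides (`k1`..`k13`, `tau1`..`tau5`,
#'   `eps1`..`eps5`, `nu`, `alpha`, `beta`).
#' @return The modified `swd_params` object (all other fields untouched).
#' @export
set_params <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 0L) {
    validate_params(params)
    return(params)
  }
  if (is.null(names(ov)) || any(names(ov) == ""))
    stop("parameter overrides must be named")
  for (nm in names(ov)) {
    val <- ov[[nm]]
    if (!is.numeric(val) || length(val) != 1L)
      stop("override '", nm, "' must be a numeric scalar")
    if (grepl("^k([1-9]|1[0-3])$", nm)) {
      params$k[[nm]] <- val
    } else if (grepl("^tau[1-5]$", nm)) {
      params$tau[[nm]] <- val
    } else if (grepl("^eps[1-5]$", nm)) {
      params$eps[[nm]] <- val
    } else if (nm %in% c("nu", "alpha", "beta")) {
      params[[nm]] <- val
    } else {
      stop("unknown model parameter '", nm, "'")
    }
  }
  validate_params(params)
  params
}

validate_params <- function(p) {
  stopifnot(inherits(p, "swd_params"))
  if (length(p$eps) != 5L || length(p$tau) != 5L || length(p$k) != 13L)
    stop("parameter vector of wrong arity: need eps[5], tau[5], k[13]")
  if (any(!is.finite(c(p$eps, p$tau, p$k, p$nu, p$alpha, p$beta))))
    stop("model parameters must be finite")
  if (any(p$k < 0)) stop("coupling strengths k1..k13 must be non-negative")
  if (any(p$tau <= 0)) stop("time scales tau1..tau5 must be positive")
  if (p$nu <= 1) stop("sigmoid steepness nu must exceed 1")
  invisible(p)
}

# Set one value on a group of constants that move together (e.g. the two
# output couplings of one interneuron population, k3 and k6).
set_group <- function(params, names, value) {
  do.call(set_params,
          c(list(params),
            stats::setNames(as.list(rep(value, length(names))), names)))
}

# Pack into the flat length-26 vector used by the compiled integrator:
# eps(5), tau(5), k(13), nu, alpha, beta.
param_vector <- function(p) {
  validate_params(p)
  c(p$eps, p$tau, p$k, p$nu, p$alpha, p$beta)
}

# 0-based index of a named parameter in the packed vector (for ramps).
param_offset <- function(name) {
  nm <- c(paste0("eps", 1:5), paste0("tau", 1:5), paste0("k", 1:13),
          "nu", "alpha", "beta")
  i <- match(name, nm)
  if (is.na(i)) stop("unknown model parameter '", name, "'")
  i - 1L
}

#' @export
print.swd_params <- function(x, ...) {
  cat("Thalamocortical field model parameters\n")
  cat("  eps:", paste(signif(x$eps, 4), collapse = " "), "\n")
  cat("  tau:", paste(signif(x$tau, 4), collapse = " "), "\n")
  cat("  k:  ", paste(signif(x$k, 4), collapse = " "), "\n")
  cat("  nu =", format(x$nu), " alpha =", x$alpha, " beta =", x$beta, "\n")
  invisible(x)
}

#' Reference initial state
#'
#' The default initial condition used throughout: activities of
#' (PY, IN1, IN2, TC, RE). In the first bistable window of the model this
#' point lies on the non-seizure side of the separatrix, so unstimulated
#' runs settle to the background equilibrium there.
#'
#' @return Named numeric vector of length 5.
#' @export
default_state <- function() {
  c(PY = 0.1724, IN1 = 0.1787, IN2 = 0.1803, TC = -0.0818, RE = 0.2775)
}

as_state <- function(x) {
  if (length(x) != 5L) stop("state vector must have length 5 (PY, IN1, IN2, TC, RE)")
  if (any(!is.finite(x))) stop("state vector must be finite")
  x <- as.numeric(x)
  names(x) <- c("PY", "IN1", "IN2", "TC", "RE")
  x
}
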