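#' Jacobian of the field model
#'
#' 5x5 Jacobian of [field_rhs()] at a state, either from the analytic
#' derivatives of the sigmoid and linear activations (default) or by
#' central finite differences with step `1e-6 * (1 + |x|)`.
#'
#' @param params parameter set.
#' @param state length-5 state.
#' @param method `"analytic"` or `"numeric"`.
#' @return 5x5 numeric matrix.
#' @export
field_jacobian <- function(params, state, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  y <- as_state(state)
  validate_params(params)
  if (method == "numeric") {
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      h <- 1e-6 * (1 + abs(y[j]))
      yp <- y; ym <- y
      yp[j] <- y[j] + h; ym[j] <- y[j] - h
      J[, j] <- (field_rhs(yp, params) - field_rhs(ym, params)) / (2 * h)
    }
    return(J)
  }
  tau <- params$tau; k <- params$k; a <- params$alpha
  f <- sigmoid_activation(y, params$nu)
  fp <- log(params$nu) * f * (1 - f)     # d/dx of the sigmoid
  J <- matrix(0, 5, 5)
  J[1, ] <- tau[1] * c(-1 + k[1] * fp[1], -k[2] * fp[2], -k[3] * fp[3], k[4] * fp[4], 0)
  J[2, ] <- tau[2] * c(k[5] * fp[1], -1, -k[6] * fp[3], 0, 0)
  J[3, ] <- tau[3] * c(k[7] * fp[1], -k[8] * fp[2], -1, 0, 0)
  J[4, ] <- tau[4] * c(k[10] * fp[1], 0, 0, -1, -k[9] * a)
  J[5, ] <- tau[5] * c(k[13] * fp[1], 0, 0, k[12] * a, -1 - k[11] * a)
  J
}

#' Locate an equilibrium by damped Newton iteration
#'
#' Newton's method on [field_rhs()] with the analytic Jacobian and step
#' halving (factor 0.5, up to 10 halvings) whenever a full step fails to
#' reduce the residual.
#'
#' @param params parameter set.
#' @param guess starting state.
#' @param tol residual max-norm for convergence.
#' @param max_iter iteration cap.
#' @return Named length-5 equilibrium state with attribute `"residual"`.
#' @export
find_equilibrium <- function(params, guess = default_state(),
                             tol = 1e-11, max_iter = 100) {
  y <- as_state(guess)
  r <- field_rhs(y, params)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol)
      return(structure(y, residual = max(abs(r))))
    step <- tryCatch(solve(field_jacobian(params, y), r),
                     error = function(e) stop("singular Jacobian in Newton iteration"))
    lambda <- 1
    for (h in 1:10) {
      y_new <- y - lambda * step
      r_new <- field_rhs(y_new, params)
      if (max(abs(r_new)) < max(abs(r))) break
      lambda <- lambda / 2
    }
    y <- y_new; r <- r_new
  }
  if (max(abs(r)) < tol) return(structure(y, residual = max(abs(r))))
  stop("Newton iteration did not converge in ", max_iter,
       " steps; last residual ", format(max(abs(r))))
}

#' Equilibrium branch over a parameter grid
#'
#' Pseudo-continuation of the equilibrium: each converged point seeds the
#' Newton solve at the next grid value. Jacobian eigenvalues and linear
#' stability are recorded per value. If the branch is lost (Newton
#' divergence) it is truncated with a warning.
#'
#' @param params parameter set.
#' @param param continued parameter name.
#' @param grid monotone numeric grid.
#' @param guess starting state for the first grid value.
#' @return Data frame of class `swd_branch`: `value`, equilibrium
#'   coordinates `PY..RE`, `max_re` (largest eigenvalue real part),
#'   `max_re_cplx` (largest real part over complex pairs, NA if none),
#'   `stable`, `residual`; full eigenvalues in `attr(, "eigenvalues")`
#'   (5-column complex matrix).
#' @export
equilibrium_branch <- function(params, param, grid, guess = default_state()) {
  d <- diff(grid)
  if (!(all(d > 0) || all(d < 0))) stop("grid must be monotone")
  n <- length(grid)
  eq <- matrix(NA_real_, n, 5, dimnames = list(NULL, names(default_state())))
  ev <- matrix(NA_complex_, n, 5)
  res <- rep(NA_real_, n)
  y <- guess
  last <- n
  for (i in seq_len(n)) {
    p_i <- set_group(params, param, grid[i])
    sol <- tryCatch(find_equilibrium(p_i, y), error = function(e) e)
    if (inherits(sol, "error")) {
      warning("branch truncated at ", param, " = ", grid[i], ": ",
              conditionMessage(sol))
      last <- i - 1L
      break
    }
    eq[i, ] <- sol
    res[i] <- attr(sol, "residual")
    ev[i, ] <- eigen(field_jacobian(p_i, sol), only.values = TRUE)$values
    y <- sol
  }
  keep <- seq_len(last)
  max_re <- apply(ev[keep, , drop = FALSE], 1, function(z) max(Re(z)))
  max_re_cplx <- apply(ev[keep, , drop = FALSE], 1, function(z) {
    cp <- z[abs(Im(z)) > 1e-9]
    if (length(cp)) max(Re(cp)) else NA_real_
  })
  out <- data.frame(value = grid[keep], eq[keep, , drop = FALSE],
                    max_re = max_re, max_re_cplx = max_re_cplx,
                    stable = max_re < 0, residual = res[keep])
  structure(out, param = param, eigenvalues = ev[keep, , drop = FALSE],
            class = c("swd_branch", "data.frame"))
}

# Real part of the leading complex eigenvalue pair at the equilibrium for
# a given parameter value, solving from `guess`.
leading_pair_re <- function(params, param, value, guess) {
  p <- set_group(params, param, value)
  eqm <- find_equilibrium(p, guess)
  z <- eigen(field_jacobian(p, eqm), only.values = TRUE)$values
  cp <- z[abs(Im(z)) > 1e-9]
  list(re = if (length(cp)) max(Re(cp)) else NA_real_,
       re_real = if (length(cp) < 5) max(Re(z[abs(Im(z)) <= 1e-9])) else -Inf,
       eq = eqm, all = z)
}

#' Locate a Hopf bifurcation on the equilibrium branch
#'
#' Bisection on the real part of the leading complex eigenvalue pair over
#' a bracket across which it changes sign. The criticality is probed by
#' simulation on the unstable side of the crossing: if the attractor
#' amplitude shrinks towards zero as the crossing is approached
#' (square-root-like growth), the Hopf is supercritical; if a
#' large-amplitude cycle is present immediately, subcritical.
#'
#' @param params parameter set.
#' @param param bifurcation parameter name.
#' @param bracket length-2 numeric: bracketing interval.
#' @param resolution final bracket width.
#' @param guess starting state for the equilibrium solves.
#' @param classify_kind probe the criticality by simulation (else kind
#'   `"HOPF"`).
#' @return List of class `swd_bifpoint`: `kind` (`"HOPF_SUPER"`,
#'   `"HOPF_SUB"`), `value` (crossing parameter value), `bracket`,
#'   `eigenvalues` (spectrum at the crossing), `probe` (amplitudes used for
#'   the criticality call, if probed).
#' @export
locate_hopf <- function(params, param, bracket, resolution = 0.002,
                        guess = default_state(), classify_kind = TRUE) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  lo <- leading_pair_re(params, param, bracket[1], guess)
  hi <- leading_pair_re(params, param, bracket[2], lo$eq)
  if (is.na(lo$re) || is.na(hi$re))
    stop("non-Hopf: no complex eigenvalue pair at a bracket end")
  if (sign(lo$re) == sign(hi$re))
    stop("no sign change of the complex-pair real part across the bracket")
  if (max(lo$re_real, hi$re_real) > 0)
    stop("non-Hopf: a real eigenvalue is positive inside the bracket")
  a <- bracket[1]; b <- bracket[2]
  fa <- lo$re
  seed <- lo$eq
  while (b - a > resolution) {
    m <- (a + b) / 2
    mid <- leading_pair_re(params, param, m, seed)
    if (is.na(mid$re)) stop("complex pair lost during bisection (non-Hopf crossing)")
    seed <- mid$eq
    if (sign(mid$re) == sign(fa)) { a <- m; fa <- mid$re } else b <- m
  }
  value <- (a + b) / 2
  at <- leading_pair_re(params, param, value, seed)
  kind <- "HOPF"
  probe <- NULL
  if (classify_kind) {
    unstable_side <- if (lo$re > 0) -1 else 1   # sign towards positive real part
    probe_amp <- function(dist) {
      v <- value + unstable_side * dist
      p <- set_group(params, param, v)
      tr <- simulate_field(p, sim_config(duration = 30, transient = 0,
                                         initial_state = at$eq + 1e-3))
      s <- oscillation_summary(cortical_mean(tr, from = 20), tr$dt)
      s$amplitude
    }
    probe <- c(near = probe_amp(4 * resolution), far = probe_amp(16 * resolution))
    # Supercritical: amplitude ~ sqrt(distance), so near/far ~ 1/2; a
    # subcritical crossing lands on the coexisting large cycle on both probes.
    kind <- if (probe["near"] < 0.7 * probe["far"]) "HOPF_SUPER" else "HOPF_SUB"
  }
  structure(list(kind = kind, value = value, bracket = c(a, b),
                 eigenvalues = at$all, probe = probe),
            class = "swd_bifpoint")
}

#' Locate a fold of limit cycles by inherited-state bisection
#'
#' Tracks the large-amplitude cycle from the bracket end where it exists
#' (`cycle_from`), inheriting end states into each probe simulation, and
#' bisects on cycle existence (post-settle amplitude above `amp_tol`).
#'
#' @param params parameter set.
#' @param param bifurcation parameter name.
#' @param bracket length-2 numeric interval; the cycle must exist at the
#'   `cycle_from` end and not at the other.
#' @param resolution final bracket width.
#' @param cycle_from `"upper"` or `"lower"`: which bracket end carries the
#'   cycle.
#' @param settle settling time (s) before the amplitude is measured over
#'   the final 10 s.
#' @param amp_tol amplitude above which a cycle is deemed present.
#' @param init initial state used to reach the cycle at the starting end.
#' @return List of class `swd_bifpoint`: `kind = "FOLD_OF_CYCLES"`, `value`
#'   (bracket midpoint), `bracket`, `amplitudes` (at the original bracket
#'   ends).
#' @export
locate_cycle_fold <- function(params, param, bracket, resolution = 0.005,
                              cycle_from = c("upper", "lower"), settle = 20,
                              amp_tol = 1e-3, init = default_state()) {
  cycle_from <- match.arg(cycle_from)
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  dur <- settle + 10
  run <- function(value, ic) {
    p <- set_group(params, param, value)
    tr <- simulate_field(p, sim_config(duration = dur, transient = 0,
                                       initial_state = ic))
    amp <- oscillation_summary(cortical_mean(tr, from = settle), tr$dt)$amplitude
    list(amp = amp, end = tr$state[nrow(tr$state), ])
  }
  start <- if (cycle_from == "upper") bracket[2] else bracket[1]
  other <- if (cycle_from == "upper") bracket[1] else bracket[2]
  s0 <- run(start, init)
  if (s0$amp <= amp_tol)
    stop("no cycle at the ", cycle_from, " bracket end (amplitude ",
         format(s0$amp), ")")
  s1 <- run(other, s0$end)
  if (s1$amp > amp_tol)
    stop("cycle persists across the whole bracket; no fold inside")
  cyc <- start; no_cyc <- other
  ic <- s0$end
  while (abs(cyc - no_cyc) > resolution) {
    m <- (cyc + no_cyc) / 2
    sm <- run(m, ic)
    if (sm$amp > amp_tol) { cyc <- m; ic <- sm$end } else no_cyc <- m
  }
  structure(list(kind = "FOLD_OF_CYCLES", value = (cyc + no_cyc) / 2,
                 bracket = sort(c(cyc, no_cyc)),
                 amplitudes = c(cycle_end = s0$amp, far_end = s1$amp)),
            class = "swd_bifpoint")
}

#' @export
print.swd_bifpoint <- function(x, ...) {
  cat(sprintf("%s at parameter value %.4f (bracket [%.4f, %.4f])\n",
              x$kind, x$value, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Bistable parameter intervals
#'
#' For each grid value, one run starts near the continued equilibrium and
#' one from a cycle-inherited state (tracked from the `cycle_from` end of
#' the grid). Grid values where the two runs settle to different labels are
#' collected into maximal intervals; each reported interval is therefore
#' backed by explicit coexistence of two attractors.
#'
#' @param params parameter set.
#' @param param scanned parameter name.
#' @param grid monotone increasing grid.
#' @param cycle_from `"upper"` or `"lower"`: grid end from which the cycle
#'   is tracked.
#' @param settle settling time (s); labels use the final 10 s.
#' @param guess seed for the equilibrium continuation.
#' @param ... classification options.
#' @return Data frame: one row per interval with `lower`, `upper`,
#'   `eq_label`, `cycle_label` (the coexisting attractor labels at the
#'   interval cells). Zero rows when no bistability is found.
#' @export
bistable_intervals <- function(params, param, grid,
                               cycle_from = c("upper", "lower"), settle = 20,
                               guess = default_state(), ...) {
  cycle_from <- match.arg(cycle_from)
  stopifnot(all(diff(grid) > 0))
  n <- length(grid)
  dur <- settle + 10
  lab <- function(p, ic) {
    tr <- simulate_field(p, sim_config(duration = dur, transient = 0,
                                       initial_state = ic))
    list(label = as.character(classify_state(cortical_mean(tr, from = settle),
                                             tr$dt, ...)),
         end = tr$state[nrow(tr$state), ])
  }
  eq_lab <- cyc_lab <- character(n)
  # Equilibrium-seeded runs, continued along the grid.
  y <- guess
  for (i in seq_len(n)) {
    p_i <- set_group(params, param, grid[i])
    eqm <- tryCatch(find_equilibrium(p_i, y), error = function(e) NULL)
    if (is.null(eqm)) { eq_lab[i] <- "FAILED"; next }
    y <- eqm
    eq_lab[i] <- lab(p_i, eqm + 1e-4)$label
  }
  # Cycle-inherited runs from the cycle-carrying end.
  order_idx <- if (cycle_from == "upper") rev(seq_len(n)) else seq_len(n)
  ic <- guess
  for (i in order_idx) {
    p_i <- set_group(params, param, grid[i])
    r <- lab(p_i, ic)
    cyc_lab[i] <- r$label
    if (!r$label %in% c("SATURATED_LOW", "SATURATED_HIGH")) ic <- r$end
  }
  bist <- eq_lab != cyc_lab & eq_lab != "FAILED"
  if (!any(bist))
    return(data.frame(lower = numeric(0), upper = numeric(0),
                      eq_label = character(0), cycle_label = character(0)))
  r <- rle(bist)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(lower = grid[starts[keep]], upper = grid[ends[keep]],
             eq_label = vapply(keep, function(j)
               names(sort(table(eq_lab[starts[j]:ends[j]]), decreasing = TRUE))[1],
               character(1)),
             cycle_label = vapply(keep, function(j)
               names(sort(table(cyc_lab[starts[j]:ends[j]]), decreasing = TRUE))[1],
               character(1)))
}
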