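#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (length 26):
//   [0..4]   eps1..eps5   additive input constants
//   [5..9]   tau1..tau5   time-scale multipliers
//   [10..22] k1..k13      coupling strengths
//   [23]     nu           sigmoid steepness
//   [24]     alpha        linear-activation slope
//   [25]     beta         linear-activation offset
// State order: PY, IN1, IN2, TC, RE.

static inline double fsig(double x, double lognu) {
  // f(x) = 1 / (1 + nu^(-x)) evaluated in the log domain
  return 1.0 / (1.0 + std::exp(-x * lognu));
}

static inline void field_deriv(const double *y, const double *p, double lognu,
                               double stim_py, double stim_in1, double *dy) {
  const double *eps = p;
  const double *tau = p + 5;
  const double *k   = p + 10;   // k[0] == k1
  const double alpha = p[24], beta = p[25];
  const double fPY  = fsig(y[0], lognu);
  const double fIN1 = fsig(y[1], lognu);
  const double fIN2 = fsig(y[2], lognu);
  const double fTC  = fsig(y[3], lognu);
  const double sTC  = alpha * y[3] + beta;
  const double sRE  = alpha * y[4] + beta;
  dy[0] = tau[0] * (eps[0] - y[0] + k[0] * fPY - k[1] * fIN1 - k[2] * fIN2 + k[3] * fTC) + stim_py;
  dy[1] = tau[1] * (eps[1] - y[1] + k[4] * fPY - k[5] * fIN2) + stim_in1;
  dy[2] = tau[2] * (eps[2] - y[2] + k[6] * fPY - k[7] * fIN1);
  dy[3] = tau[3] * (eps[3] - y[3] - k[8] * sRE + k[9] * fPY);
  dy[4] = tau[4] * (eps[4] - y[4] - k[10] * sRE + k[11] * sTC + k[12] * fPY);
}

// Sum of active rectangular-pulse amplitudes at time t for each cortical target.
static inline void pulse_input(const NumericMatrix &events, double t,
                               double *stim_py, double *stim_in1) {
  *stim_py = 0.0; *stim_in1 = 0.0;
  for (int e = 0; e < events.nrow(); ++e) {
    if (events(e, 3) != 1.0) continue;           // mode 1 == rectangular pulse
    double t0 = events(e, 0), t1 = t0 + events(e, 4);
    if (t >= t0 && t < t1) {
      *stim_py  += events(e, 1);
      *stim_in1 += events(e, 2);
    }
  }
}

//' Fixed-step RK4 integration of the thalamocortical field model.
//'
//' @param p numeric parameter vector of length 26 (see layout above).
//' @param y0 initial state (PY, IN1, IN2, TC, RE).
//' @param dt step size in seconds.
//' @param nsteps number of steps; output has nsteps + 1 rows.
//' @param events matrix with columns (time, amp_py, amp_in1, mode, duration);
//'   amplitudes are signed; mode 0 = instantaneous state jump applied at the
//'   first grid point at or after `time`, mode 1 = rectangular pulse added to
//'   the PY/IN1 derivatives over [time, time + duration).
//' @param ramp_idx 0-based index into `p` of a linearly ramped parameter, or -1.
//' @param ramp_t0,ramp_t1,ramp_v0,ramp_v1 ramp window and values (clamped).
//' @noRd
// [[Rcpp::export(name = ".rk4_field")]]
NumericMatrix rk4_field(NumericVector p, NumericVector y0, double dt, int nsteps,
                        NumericMatrix events, int ramp_idx,
                        double ramp_t0, double ramp_t1,
                        double ramp_v0, double ramp_v1) {
  if (p.size() != 26) stop("parameter vector must have length 26, got %d", (int)p.size());
  if (y0.size() != 5) stop("state vector must have length 5");
  if (events.ncol() != 5 && events.nrow() > 0) stop("events must have 5 columns");

  std::vector<double> par(p.begin(), p.end());
  const double lognu = std::log(p[23]);
  const bool ramp = ramp_idx >= 0;
  const bool have_pulses = [&]() {
    for (int e = 0; e < events.nrow(); ++e) if (events(e, 3) == 1.0) return true;
    return false;
  }();

  // Precompute grid node for each state-jump event.
  std::vector<int> jump_node(events.nrow(), -1);
  for (int e = 0; e < events.nrow(); ++e)
    if (events(e, 3) == 0.0)
      jump_node[e] = (int)std::ceil(events(e, 0) / dt - 1e-9);

  NumericMatrix out(nsteps + 1, 5);
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int j = 0; j < 5; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }

  auto set_ramp = [&](double t) {
    if (!ramp) return;
    double v;
    if (t <= ramp_t0) v = ramp_v0;
    else if (t >= ramp_t1) v = ramp_v1;
    else v = ramp_v0 + (ramp_v1 - ramp_v0) * (t - ramp_t0) / (ramp_t1 - ramp_t0);
    par[ramp_idx] = v;
  };

  double spy = 0.0, sin1 = 0.0;
  for (int i = 0; i < nsteps; ++i) {
    const double t = i * dt;

    for (int e = 0; e < (int)jump_node.size(); ++e)
      if (jump_node[e] == i) {
        y[0] += events(e, 1);
        y[1] += events(e, 2);
        for (int j = 0; j < 5; ++j) out(i, j) = y[j];
      }

    set_ramp(t);
    if (have_pulses) pulse_input(events, t, &spy, &sin1);
    field_deriv(y, par.data(), lognu, spy, sin1, k1);

    set_ramp(t + 0.5 * dt);
    if (have_pulses) pulse_input(events, t + 0.5 * dt, &spy, &sin1);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    field_deriv(tmp, par.data(), lognu, spy, sin1, k2);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    field_deriv(tmp, par.data(), lognu, spy, sin1, k3);

    set_ramp(t + dt);
    if (have_pulses) pulse_input(events, t + dt, &spy, &sin1);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + dt * k3[j];
    field_deriv(tmp, par.data(), lognu, spy, sin1, k4);

    for (int j = 0; j < 5; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      out(i + 1, j) = y[j];
    }

    if ((i & 0x3FF) == 0 || i == nsteps - 1) {
      for (int j = 0; j < 5; ++j)
        if (!std::isfinite(y[j]))
          stop("non-finite state at step %d (t = %.3f s); check parameter set", i + 1, t);
    }
  }

  // Jump events scheduled exactly at the final node.
  for (int e = 0; e < (int)jump_node.size(); ++e)
    if (jump_node[e] == nsteps) {
      out(nsteps, 0) += events(e, 1);
      out(nsteps, 1) += events(e, 2);
    }

  return out;
}
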