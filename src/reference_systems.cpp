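#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reference dynamical systems integrated with fixed-step classical RK4.
// system_id: 0 = Lorenz (p = sigma, rho, beta);
//            1 = damped-z harmonic oscillator (p[0] = omega), max exponent 0.

static inline void deriv(int system_id, const double *s, double *ds,
                         const double *p) {
  if (system_id == 0) {
    ds[0] = p[0] * (s[1] - s[0]);
    ds[1] = s[0] * (p[1] - s[2]) - s[1];
    ds[2] = s[0] * s[1] - p[2] * s[2];
  } else {
    ds[0] = s[1];
    ds[1] = -p[0] * p[0] * s[0];
    ds[2] = -s[2];
  }
}

// Jacobian-vector product for the tangent dynamics.
static inline void jac_vec(int system_id, const double *s, const double *v,
                           double *jv, const double *p) {
  if (system_id == 0) {
    jv[0] = p[0] * (v[1] - v[0]);
    jv[1] = (p[1] - s[2]) * v[0] - v[1] - s[0] * v[2];
    jv[2] = s[1] * v[0] + s[0] * v[1] - p[2] * v[2];
  } else {
    jv[0] = v[1];
    jv[1] = -p[0] * p[0] * v[0];
    jv[2] = -v[2];
  }
}

static void rk4_step(int system_id, double *s, double dt, const double *p) {
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  deriv(system_id, s, k1, p);
  for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  deriv(system_id, tmp, k2, p);
  for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  deriv(system_id, tmp, k3, p);
  for (int i = 0; i < 3; ++i) tmp[i] = s[i] + dt * k3[i];
  deriv(system_id, tmp, k4, p);
  for (int i = 0; i < 3; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Combined RK4 step for state + tangent vector (variational equations).
static void rk4_step_tangent(int system_id, double *s, double *v, double dt,
                             const double *p) {
  double ks[4][3], kv[4][3], ts[3], tv[3];
  deriv(system_id, s, ks[0], p);
  jac_vec(system_id, s, v, kv[0], p);
  for (int i = 0; i < 3; ++i) {
    ts[i] = s[i] + 0.5 * dt * ks[0][i];
    tv[i] = v[i] + 0.5 * dt * kv[0][i];
  }
  deriv(system_id, ts, ks[1], p);
  jac_vec(system_id, ts, tv, kv[1], p);
  for (int i = 0; i < 3; ++i) {
    ts[i] = s[i] + 0.5 * dt * ks[1][i];
    tv[i] = v[i] + 0.5 * dt * kv[1][i];
  }
  deriv(system_id, ts, ks[2], p);
  jac_vec(system_id, ts, tv, kv[2], p);
  for (int i = 0; i < 3; ++i) {
    ts[i] = s[i] + dt * ks[2][i];
    tv[i] = v[i] + dt * kv[2][i];
  }
  deriv(system_id, ts, ks[3], p);
  jac_vec(system_id, ts, tv, kv[3], p);
  for (int i = 0; i < 3; ++i) {
    s[i] += dt / 6.0 * (ks[0][i] + 2 * ks[1][i] + 2 * ks[2][i] + ks[3][i]);
    v[i] += dt / 6.0 * (kv[0][i] + 2 * kv[1][i] + 2 * kv[2][i] + kv[3][i]);
  }
}

// Integrate and sample a trajectory: discard `discard_steps` RK4 steps, then
// record every `every`-th step, n_out rows.
// [[Rcpp::export(name = ".trajectory_cpp")]]
NumericMatrix trajectory_cpp(int system_id, NumericVector init,
                             NumericVector params, double dt, int discard_steps,
                             int every, int n_out) {
  double s[3] = {init[0], init[1], init[2]};
  double p[3] = {0, 0, 0};
  for (int i = 0; i < params.size() && i < 3; ++i) p[i] = params[i];
  for (int i = 0; i < discard_steps; ++i) rk4_step(system_id, s, dt, p);
  NumericMatrix out(n_out, 3);
  for (int r = 0; r < n_out; ++r) {
    out(r, 0) = s[0];
    out(r, 1) = s[1];
    out(r, 2) = s[2];
    for (int i = 0; i < every; ++i) rk4_step(system_id, s, dt, p);
  }
  return out;
}

// Largest Lyapunov exponent by the Benettin tangent-space method: evolve a
// tangent vector along the trajectory, renormalise every step, and average the
// log stretch rates after a transient discard. Units: nats per unit time.
// [[Rcpp::export(name = ".benettin_cpp")]]
double benettin_cpp(int system_id, NumericVector init, NumericVector params,
                    double dt, double t_discard, double t_total) {
  double s[3] = {init[0], init[1], init[2]};
  double v[3] = {1.0, 0.0, 0.0};
  double p[3] = {0, 0, 0};
  for (int i = 0; i < params.size() && i < 3; ++i) p[i] = params[i];
  const int n_disc = (int)std::ceil(t_discard / dt);
  const int n_main = (int)std::ceil(t_total / dt);
  for (int i = 0; i < n_disc; ++i) {
    rk4_step_tangent(system_id, s, v, dt, p);
    double nrm = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    for (int k = 0; k < 3; ++k) v[k] /= nrm;
  }
  double acc = 0.0;
  for (int i = 0; i < n_main; ++i) {
    rk4_step_tangent(system_id, s, v, dt, p);
    double nrm = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    acc += std::log(nrm);
    for (int k = 0; k < 3; ++k) v[k] /= nrm;
  }
  return acc / (n_main * dt);
}
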