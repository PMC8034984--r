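#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quaternion product a (x) b, Hamilton convention, (w, x, y, z).
static inline void quat_mul(const double *a, const double *b, double *out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static inline void quat_normalize(double *q) {
  const double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

// Unit quaternion for a rotation by the vector theta (axis * angle).
static inline void quat_exp(const double *theta, double *dq) {
  const double a = std::sqrt(theta[0] * theta[0] + theta[1] * theta[1] +
                             theta[2] * theta[2]);
  if (a < 1e-14) {
    dq[0] = 1.0; dq[1] = 0.5 * theta[0]; dq[2] = 0.5 * theta[1];
    dq[3] = 0.5 * theta[2];
    quat_normalize(dq);
    return;
  }
  const double h = 0.5 * a, s = std::sin(h) / a;
  dq[0] = std::cos(h);
  dq[1] = s * theta[0]; dq[2] = s * theta[1]; dq[3] = s * theta[2];
}

static inline void quat_to_rot(const double *q, double R[9]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z);
  R[1] = 2 * (x * y - w * z);
  R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z);
  R[4] = 1 - 2 * (x * x + z * z);
  R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y);
  R[7] = 2 * (y * z + w * x);
  R[8] = 1 - 2 * (x * x + y * y);
}

// Overdamped rigid-body Brownian dynamics with a body-frame 6x6 diffusion
// tensor. Lchol is any square root of 2*D*dt, i.e. Lchol %*% t(Lchol) =
// 2*D*dt (rows: translation xyz then rotation xyz, body frame; need not be
// triangular). Each step draws a 6-vector
// Gaussian displacement in the body frame, maps the translational part to
// the lab frame through the current orientation, and composes the rotational
// part as a body-frame rotation (quaternion exponential map). Uses R's RNG.
// [[Rcpp::export]]
List run_bd_cpp(NumericMatrix Lchol, NumericVector com0, NumericVector quat0,
                int n_steps, int snapshot_every) {
  const int n_snap = n_steps / snapshot_every + 1;
  NumericMatrix com(n_snap, 3);
  NumericMatrix quat(n_snap, 4);
  double c[3] = {com0[0], com0[1], com0[2]};
  double q[4] = {quat0[0], quat0[1], quat0[2], quat0[3]};
  quat_normalize(q);
  for (int k = 0; k < 3; ++k) com(0, k) = c[k];
  for (int k = 0; k < 4; ++k) quat(0, k) = q[k];

  double z[6], d[6], R[9], dq[4], qn[4];
  int isnap = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < 6; ++k) z[k] = norm_rand();
    for (int i = 0; i < 6; ++i) {
      double s = 0.0;
      for (int j = 0; j < 6; ++j) s += Lchol(i, j) * z[j];
      d[i] = s;
    }
    quat_to_rot(q, R);
    // body-frame translation -> lab frame
    c[0] += R[0] * d[0] + R[1] * d[1] + R[2] * d[2];
    c[1] += R[3] * d[0] + R[4] * d[1] + R[5] * d[2];
    c[2] += R[6] * d[0] + R[7] * d[1] + R[8] * d[2];
    // body-frame rotation
    quat_exp(d + 3, dq);
    quat_mul(q, dq, qn);
    for (int k = 0; k < 4; ++k) q[k] = qn[k];
    quat_normalize(q);
    if (step % snapshot_every == 0) {
      for (int k = 0; k < 3; ++k) com(isnap, k) = c[k];
      for (int k = 0; k < 4; ++k) quat(isnap, k) = q[k];
      ++isnap;
    }
  }
  return List::create(_["com"] = com, _["quat"] = quat);
}

// Free point particle underdamped Langevin dynamics, symmetric splitting:
// drift dt/2, exact Ornstein-Uhlenbeck velocity update, drift dt/2.
// The velocity process is sampled exactly at every step.
// [[Rcpp::export]]
List run_langevin_cpp(double mass, double gamma, double kBT, double dt,
                      int n_steps, NumericVector v0, int snapshot_every) {
  const int n_snap = n_steps / snapshot_every + 1;
  NumericMatrix pos(n_snap, 3);
  NumericMatrix vel(n_snap, 3);
  double x[3] = {0.0, 0.0, 0.0};
  double v[3] = {v0[0], v0[1], v0[2]};
  for (int k = 0; k < 3; ++k) vel(0, k) = v[k];

  double c1 = 1.0, c2 = 0.0;
  if (gamma > 0) {
    c1 = std::exp(-gamma * dt / mass);
    c2 = std::sqrt(kBT * (1.0 - c1 * c1) / mass);
  }
  int isnap = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < 3; ++k) x[k] += 0.5 * dt * v[k];
    if (gamma > 0)
      for (int k = 0; k < 3; ++k) v[k] = c1 * v[k] + c2 * norm_rand();
    for (int k = 0; k < 3; ++k) x[k] += 0.5 * dt * v[k];
    if (step % snapshot_every == 0) {
      for (int k = 0; k < 3; ++k) { pos(isnap, k) = x[k]; vel(isnap, k) = v[k]; }
      ++isnap;
    }
  }
  return List::create(_["pos"] = pos, _["vel"] = vel);
}
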