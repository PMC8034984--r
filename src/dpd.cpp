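#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- small helpers --------------------------------------------------------

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

// Invert a symmetric positive-definite 3x3 matrix.
static inline void inv3(const double A[9], double Ai[9]) {
  const double det =
      A[0] * (A[4] * A[8] - A[5] * A[7]) -
      A[1] * (A[3] * A[8] - A[5] * A[6]) +
      A[2] * (A[3] * A[7] - A[4] * A[6]);
  const double id = 1.0 / det;
  Ai[0] = (A[4] * A[8] - A[5] * A[7]) * id;
  Ai[1] = (A[2] * A[7] - A[1] * A[8]) * id;
  Ai[2] = (A[1] * A[5] - A[2] * A[4]) * id;
  Ai[3] = (A[5] * A[6] - A[3] * A[8]) * id;
  Ai[4] = (A[0] * A[8] - A[2] * A[6]) * id;
  Ai[5] = (A[2] * A[3] - A[0] * A[5]) * id;
  Ai[6] = (A[3] * A[7] - A[4] * A[6]) * id;
  Ai[7] = (A[1] * A[6] - A[0] * A[7]) * id;
  Ai[8] = (A[0] * A[4] - A[1] * A[3]) * id;
}

struct DPDWork {
  int Nf, Nb, Nt;
  double box[3], rc, rc2, a, gamma, sigma, dt, isqdt;
  int ncell[3];
  bool use_cells;
  std::vector<double> px, py, pz;   // wrapped positions, all particles
  std::vector<double> vx, vy, vz;   // velocities, all particles
  std::vector<double> fx, fy, fz;   // forces, all particles
  std::vector<double> relx, rely, relz; // body bead offsets from COM (lab)
  std::vector<int> head, nxt;
  long n_zero_dist;
};

static inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against rounding
  return x;
}

static void pair_interact(DPDWork &w, int i, int j) {
  double dx = w.px[i] - w.px[j];
  double dy = w.py[i] - w.py[j];
  double dz = w.pz[i] - w.pz[j];
  // minimum image
  dx -= w.box[0] * std::nearbyint(dx / w.box[0]);
  dy -= w.box[1] * std::nearbyint(dy / w.box[1]);
  dz -= w.box[2] * std::nearbyint(dz / w.box[2]);
  const double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= w.rc2) return;
  // both beads on the rigid body: internal forces are irrelevant to a rigid unit
  if (i >= w.Nf && j >= w.Nf) return;
  double r = std::sqrt(r2);
  double ex, ey, ez;
  if (r < 1e-12) { // coincident centres: deterministic fallback direction
    ex = 1.0; ey = 0.0; ez = 0.0; r = 0.0;
    w.n_zero_dist++;
  } else {
    ex = dx / r; ey = dy / r; ez = dz / r;
  }
  const double wr = 1.0 - r / w.rc; // omega_R; omega_D = omega_R^2
  const double vdotr = (w.vx[i] - w.vx[j]) * ex + (w.vy[i] - w.vy[j]) * ey +
                       (w.vz[i] - w.vz[j]) * ez;
  const double xi = norm_rand();
  const double fs = w.a * wr - w.gamma * wr * wr * vdotr +
                    w.sigma * wr * xi * w.isqdt;
  w.fx[i] += fs * ex; w.fy[i] += fs * ey; w.fz[i] += fs * ez;
  w.fx[j] -= fs * ex; w.fy[j] -= fs * ey; w.fz[j] -= fs * ez;
}

// Evaluate all pairwise DPD forces (conservative + dissipative + random).
static void compute_forces(DPDWork &w) {
  std::fill(w.fx.begin(), w.fx.end(), 0.0);
  std::fill(w.fy.begin(), w.fy.end(), 0.0);
  std::fill(w.fz.begin(), w.fz.end(), 0.0);
  if (!w.use_cells) {
    for (int i = 0; i < w.Nt; ++i)
      for (int j = i + 1; j < w.Nt; ++j) pair_interact(w, i, j);
    return;
  }
  const int ncx = w.ncell[0], ncy = w.ncell[1], ncz = w.ncell[2];
  const int ncells = ncx * ncy * ncz;
  std::fill(w.head.begin(), w.head.end(), -1);
  for (int i = 0; i < w.Nt; ++i) {
    int cx = (int)(w.px[i] / w.box[0] * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)(w.py[i] / w.box[1] * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    int cz = (int)(w.pz[i] / w.box[2] * ncz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
    const int c = (cz * ncy + cy) * ncx + cx;
    w.nxt[i] = w.head[c];
    w.head[c] = i;
  }
  // half stencil: self cell + 13 neighbours, each pair visited exactly once
  static const int off[13][3] = {
      {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
      {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
      {1, -1, -1}};
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx) {
        const int c = (cz * ncy + cy) * ncx + cx;
        for (int i = w.head[c]; i != -1; i = w.nxt[i])
          for (int j = w.nxt[i]; j != -1; j = w.nxt[j]) pair_interact(w, i, j);
        for (int s = 0; s < 13; ++s) {
          const int cx2 = (cx + off[s][0] + ncx) % ncx;
          const int cy2 = (cy + off[s][1] + ncy) % ncy;
          const int cz2 = (cz + off[s][2] + ncz) % ncz;
          const int c2 = (cz2 * ncy + cy2) * ncx + cx2;
          for (int i = w.head[c]; i != -1; i = w.nxt[i])
            for (int j = w.head[c2]; j != -1; j = w.nxt[j])
              pair_interact(w, i, j);
        }
      }
  (void)ncells;
}

// DPD simulation of a fluid of unit-mass particles with an optional embedded
// rigid body, integrated with the modified velocity-Verlet scheme
// (Groot-Warren, prediction parameter lambda). The body is advanced as one
// rigid unit: net force/torque about the COM drive the COM velocity and the
// angular momentum; orientation is a unit quaternion renormalized each step.
// Uses R's RNG stream; pair random numbers are drawn in a fixed pair order.
// [[Rcpp::export]]
List run_dpd_cpp(NumericMatrix fluid_pos, NumericMatrix fluid_vel,
                 NumericMatrix body_pos, double body_mass,
                 NumericMatrix inertia_body, NumericVector com0,
                 NumericVector quat0, double a, double gamma, double sigma,
                 double rc, NumericVector box, double dt, double lambda,
                 int n_steps, int equil_steps, int snapshot_every,
                 double vcap) {
  DPDWork w;
  w.Nf = fluid_pos.nrow();
  w.Nb = body_pos.nrow();
  w.Nt = w.Nf + w.Nb;
  for (int k = 0; k < 3; ++k) w.box[k] = box[k];
  w.rc = rc; w.rc2 = rc * rc; w.a = a; w.gamma = gamma; w.sigma = sigma;
  w.dt = dt; w.isqdt = (dt > 0) ? 1.0 / std::sqrt(dt) : 0.0;
  w.n_zero_dist = 0;
  w.use_cells = true;
  for (int k = 0; k < 3; ++k) {
    w.ncell[k] = (int)std::floor(w.box[k] / rc);
    if (w.ncell[k] < 3) w.use_cells = false;
  }
  w.px.resize(w.Nt); w.py.resize(w.Nt); w.pz.resize(w.Nt);
  w.vx.resize(w.Nt); w.vy.resize(w.Nt); w.vz.resize(w.Nt);
  w.fx.resize(w.Nt); w.fy.resize(w.Nt); w.fz.resize(w.Nt);
  w.relx.resize(w.Nb); w.rely.resize(w.Nb); w.relz.resize(w.Nb);
  if (w.use_cells) {
    w.head.resize(w.ncell[0] * w.ncell[1] * w.ncell[2]);
    w.nxt.resize(w.Nt);
  }
  for (int i = 0; i < w.Nf; ++i) {
    w.px[i] = wrap1(fluid_pos(i, 0), w.box[0]);
    w.py[i] = wrap1(fluid_pos(i, 1), w.box[1]);
    w.pz[i] = wrap1(fluid_pos(i, 2), w.box[2]);
    w.vx[i] = fluid_vel(i, 0);
    w.vy[i] = fluid_vel(i, 1);
    w.vz[i] = fluid_vel(i, 2);
  }

  // rigid body state
  double com[3] = {com0[0], com0[1], com0[2]};   // unwrapped
  double q[4] = {quat0[0], quat0[1], quat0[2], quat0[3]};
  quat_normalize(q);
  double V[3] = {0, 0, 0};      // body COM velocity
  double L[3] = {0, 0, 0};      // body angular momentum, lab frame
  double Fb[3], Tb[3], Fb_old[3], Tb_old[3];
  double Ib[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      Ib[3 * r + c] = (w.Nb > 0) ? inertia_body(r, c) : 0.0;

  double R[9], Ilab[9], Iinv[9], tmp[9], omega[3] = {0, 0, 0};

  // refresh wrapped body bead positions/velocities from (com, q, V, omega)
  auto sync_body = [&](void) {
    if (w.Nb == 0) return;
    quat_to_rot(q, R);
    for (int b = 0; b < w.Nb; ++b) {
      const double px = body_pos(b, 0), py = body_pos(b, 1), pz = body_pos(b, 2);
      const double rx = R[0] * px + R[1] * py + R[2] * pz;
      const double ry = R[3] * px + R[4] * py + R[5] * pz;
      const double rz = R[6] * px + R[7] * py + R[8] * pz;
      w.relx[b] = rx; w.rely[b] = ry; w.relz[b] = rz;
      w.px[w.Nf + b] = wrap1(com[0] + rx, w.box[0]);
      w.py[w.Nf + b] = wrap1(com[1] + ry, w.box[1]);
      w.pz[w.Nf + b] = wrap1(com[2] + rz, w.box[2]);
      w.vx[w.Nf + b] = V[0] + omega[1] * rz - omega[2] * ry;
      w.vy[w.Nf + b] = V[1] + omega[2] * rx - omega[0] * rz;
      w.vz[w.Nf + b] = V[2] + omega[0] * ry - omega[1] * rx;
    }
  };

  auto body_force_torque = [&](void) {
    Fb[0] = Fb[1] = Fb[2] = Tb[0] = Tb[1] = Tb[2] = 0.0;
    for (int b = 0; b < w.Nb; ++b) {
      const int i = w.Nf + b;
      Fb[0] += w.fx[i]; Fb[1] += w.fy[i]; Fb[2] += w.fz[i];
      Tb[0] += w.rely[b] * w.fz[i] - w.relz[b] * w.fy[i];
      Tb[1] += w.relz[b] * w.fx[i] - w.relx[b] * w.fz[i];
      Tb[2] += w.relx[b] * w.fy[i] - w.rely[b] * w.fx[i];
    }
  };

  auto update_omega = [&](const double *Lv) {
    if (w.Nb == 0) return;
    quat_to_rot(q, R);
    // Ilab = R Ib R^T
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += R[3 * r + k] * Ib[3 * k + c];
        tmp[3 * r + c] = s;
      }
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += tmp[3 * r + k] * R[3 * c + k];
        Ilab[3 * r + c] = s;
      }
    inv3(Ilab, Iinv);
    for (int r = 0; r < 3; ++r)
      omega[r] = Iinv[3 * r] * Lv[0] + Iinv[3 * r + 1] * Lv[1] +
                 Iinv[3 * r + 2] * Lv[2];
  };

  sync_body();
  compute_forces(w);
  body_force_torque();

  const int n_snap = n_steps / snapshot_every + 1;
  NumericVector snap_step(n_snap), temperature(n_snap);
  NumericMatrix com_out(n_snap, 3), quat_out(n_snap, 4), mom_out(n_snap, 3);
  int isnap = 0;

  auto record = [&](int step) {
    snap_step[isnap] = step;
    double ke = 0, Px = 0, Py = 0, Pz = 0;
    for (int i = 0; i < w.Nf; ++i) {
      ke += w.vx[i] * w.vx[i] + w.vy[i] * w.vy[i] + w.vz[i] * w.vz[i];
      Px += w.vx[i]; Py += w.vy[i]; Pz += w.vz[i];
    }
    temperature[isnap] = (w.Nf > 0) ? ke / (3.0 * w.Nf) : NA_REAL;
    mom_out(isnap, 0) = Px + body_mass * V[0];
    mom_out(isnap, 1) = Py + body_mass * V[1];
    mom_out(isnap, 2) = Pz + body_mass * V[2];
    for (int k = 0; k < 3; ++k) com_out(isnap, k) = com[k];
    for (int k = 0; k < 4; ++k) quat_out(isnap, k) = q[k];
    ++isnap;
  };

  std::vector<double> vtx(w.Nf), vty(w.Nf), vtz(w.Nf); // saved v(t)
  std::vector<double> fox(w.Nf), foy(w.Nf), foz(w.Nf); // saved f(t)
  const double vcap2 = vcap * vcap;
  const int total_steps = equil_steps + n_steps;

  for (int step = 0; step < total_steps; ++step) {
    if (step == equil_steps) record(0);
    // positions + velocity prediction (Groot-Warren lambda step)
    for (int i = 0; i < w.Nf; ++i) {
      w.px[i] = wrap1(w.px[i] + dt * w.vx[i] + 0.5 * dt * dt * w.fx[i], w.box[0]);
      w.py[i] = wrap1(w.py[i] + dt * w.vy[i] + 0.5 * dt * dt * w.fy[i], w.box[1]);
      w.pz[i] = wrap1(w.pz[i] + dt * w.vz[i] + 0.5 * dt * dt * w.fz[i], w.box[2]);
      vtx[i] = w.vx[i]; vty[i] = w.vy[i]; vtz[i] = w.vz[i];
      fox[i] = w.fx[i]; foy[i] = w.fy[i]; foz[i] = w.fz[i];
      w.vx[i] += lambda * dt * w.fx[i];
      w.vy[i] += lambda * dt * w.fy[i];
      w.vz[i] += lambda * dt * w.fz[i];
    }
    double Vt[3] = {0, 0, 0}, Lt[3] = {0, 0, 0};
    if (w.Nb > 0) {
      for (int k = 0; k < 3; ++k) {
        com[k] += dt * V[k] + 0.5 * dt * dt * Fb[k] / body_mass;
        Vt[k] = V[k];
        Lt[k] = L[k];
        V[k] += lambda * dt * Fb[k] / body_mass;
        L[k] += lambda * dt * Tb[k];
        Fb_old[k] = Fb[k]; Tb_old[k] = Tb[k];
      }
      update_omega(L);
      // first-order quaternion update with the predicted angular velocity;
      // lab-frame angular increment composes on the left
      double lab_rot[4] = {1.0, 0.5 * dt * omega[0], 0.5 * dt * omega[1],
                           0.5 * dt * omega[2]};
      double qn[4];
      quat_mul(lab_rot, q, qn);
      for (int k = 0; k < 4; ++k) q[k] = qn[k];
      quat_normalize(q);
      sync_body();
    }
    compute_forces(w);
    body_force_torque();
    // velocity corrector with the new forces
    for (int i = 0; i < w.Nf; ++i) {
      w.vx[i] = vtx[i] + 0.5 * dt * (fox[i] + w.fx[i]);
      w.vy[i] = vty[i] + 0.5 * dt * (foy[i] + w.fy[i]);
      w.vz[i] = vtz[i] + 0.5 * dt * (foz[i] + w.fz[i]);
    }
    if (w.Nb > 0) {
      for (int k = 0; k < 3; ++k) {
        V[k] = Vt[k] + 0.5 * dt * (Fb_old[k] + Fb[k]) / body_mass;
        L[k] = Lt[k] + 0.5 * dt * (Tb_old[k] + Tb[k]);
      }
      update_omega(L);
      sync_body(); // refresh body bead velocities for the next force pass
    }
    if (vcap > 0) {
      for (int i = 0; i < w.Nf; ++i) {
        const double v2 = w.vx[i] * w.vx[i] + w.vy[i] * w.vy[i] + w.vz[i] * w.vz[i];
        if (v2 > vcap2)
          stop("DPD velocity blow-up: |v| exceeded cap at step %d", step);
      }
    }
    if (step >= equil_steps && (step - equil_steps + 1) % snapshot_every == 0)
      record(step - equil_steps + 1);
  }

  if (isnap == 0) record(0); // zero production steps: initial snapshot only

  NumericMatrix fpos(w.Nf, 3), fvel(w.Nf, 3);
  for (int i = 0; i < w.Nf; ++i) {
    fpos(i, 0) = w.px[i]; fpos(i, 1) = w.py[i]; fpos(i, 2) = w.pz[i];
    fvel(i, 0) = w.vx[i]; fvel(i, 1) = w.vy[i]; fvel(i, 2) = w.vz[i];
  }
  return List::create(
      _["step"] = snap_step, _["com"] = com_out, _["quat"] = quat_out,
      _["temperature"] = temperature, _["momentum"] = mom_out,
      _["fluid_pos"] = fpos, _["fluid_vel"] = fvel,
      _["n_zero_dist"] = (double)w.n_zero_dist);
}
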