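#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotation matrix (body -> lab) from a unit quaternion (w, x, y, z).
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

static inline double sinc(double x) {
  if (std::fabs(x) < 1e-12) return 1.0;
  return std::sin(x) / x;
}

// Coherent ISF pair sum over bead pairs, averaged over time origins.
//
// pos:  N x 3 body-frame bead coordinates
// b:    N scattering lengths
// com:  n x 3 centre-of-mass track (lab frame, unwrapped)
// quat: n x 4 unit quaternions (body -> lab)
// origins, lags: 0-based frame indices; every origin+lag must be < n
// mode: 0 = total (rotate at both times, COM at both times)
//       1 = rot   (rotate at both times, COM removed)
//       2 = trans (orientation frozen at the origin, COM at both times)
//
// Returns an nQ x nLag matrix of the *unnormalized* pair sum
//   mean over origins of sum_{m,n} b_m b_n sinc(Q |r_m(t0) - r_n(t0+lag)|).
// [[Rcpp::export]]
NumericMatrix isf_pairsum_cpp(NumericMatrix pos, NumericVector b,
                              NumericMatrix com, NumericMatrix quat,
                              IntegerVector origins, IntegerVector lags,
                              NumericVector Q, int mode) {
  const int N = pos.nrow();
  const int nO = origins.size();
  const int nL = lags.size();
  const int nQ = Q.size();
  NumericMatrix out(nQ, nL);

  std::vector<double> A(3 * N), B(3 * N);
  double R0[9], R1[9], q0[4], q1[4];

  for (int io = 0; io < nO; ++io) {
    const int t0 = origins[io];
    for (int k = 0; k < 4; ++k) q0[k] = quat(t0, k);
    quat_to_rot(q0, R0);
    const double c0x = com(t0, 0), c0y = com(t0, 1), c0z = com(t0, 2);
    // positions at the origin
    for (int i = 0; i < N; ++i) {
      const double px = pos(i, 0), py = pos(i, 1), pz = pos(i, 2);
      double x = R0[0] * px + R0[1] * py + R0[2] * pz;
      double y = R0[3] * px + R0[4] * py + R0[5] * pz;
      double z = R0[6] * px + R0[7] * py + R0[8] * pz;
      if (mode != 1) { x += c0x; y += c0y; z += c0z; }
      A[3 * i] = x; A[3 * i + 1] = y; A[3 * i + 2] = z;
    }
    for (int il = 0; il < nL; ++il) {
      const int t1 = t0 + lags[il];
      const double *Ruse = R0;
      if (mode != 2) {
        for (int k = 0; k < 4; ++k) q1[k] = quat(t1, k);
        quat_to_rot(q1, R1);
        Ruse = R1;
      }
      const double c1x = com(t1, 0), c1y = com(t1, 1), c1z = com(t1, 2);
      for (int i = 0; i < N; ++i) {
        const double px = pos(i, 0), py = pos(i, 1), pz = pos(i, 2);
        double x = Ruse[0] * px + Ruse[1] * py + Ruse[2] * pz;
        double y = Ruse[3] * px + Ruse[4] * py + Ruse[5] * pz;
        double z = Ruse[6] * px + Ruse[7] * py + Ruse[8] * pz;
        if (mode != 1) { x += c1x; y += c1y; z += c1z; }
        B[3 * i] = x; B[3 * i + 1] = y; B[3 * i + 2] = z;
      }
      // double sum over bead pairs (cross-time: not symmetric in m,n)
      std::vector<double> acc(nQ, 0.0);
      const double *qv = &Q[0];
      for (int m = 0; m < N; ++m) {
        const double ax = A[3 * m], ay = A[3 * m + 1], az = A[3 * m + 2];
        const double bm = b[m];
        for (int n = 0; n < N; ++n) {
          const double dx = ax - B[3 * n];
          const double dy = ay - B[3 * n + 1];
          const double dz = az - B[3 * n + 2];
          const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          const double w = bm * b[n];
          for (int iq = 0; iq < nQ; ++iq)
            acc[iq] += w * sinc(qv[iq] * r);
        }
      }
      for (int iq = 0; iq < nQ; ++iq) out(iq, il) += acc[iq];
    }
  }
  for (int il = 0; il < nL; ++il)
    for (int iq = 0; iq < nQ; ++iq) out(iq, il) /= nO;
  return out;
}

// Centre-of-mass ISF: mean over origins of sinc(Q |dr_c(lag)|).
// [[Rcpp::export]]
NumericMatrix isf_com_cpp(NumericMatrix com, IntegerVector origins,
                          IntegerVector lags, NumericVector Q) {
  const int nO = origins.size();
  const int nL = lags.size();
  const int nQ = Q.size();
  NumericMatrix out(nQ, nL);
  for (int io = 0; io < nO; ++io) {
    const int t0 = origins[io];
    for (int il = 0; il < nL; ++il) {
      const int t1 = t0 + lags[il];
      const double dx = com(t0, 0) - com(t1, 0);
      const double dy = com(t0, 1) - com(t1, 1);
      const double dz = com(t0, 2) - com(t1, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int iq = 0; iq < nQ; ++iq) out(iq, il) += sinc(Q[iq] * r);
    }
  }
  for (int il = 0; il < nL; ++il)
    for (int iq = 0; iq < nQ; ++iq) out(iq, il) /= nO;
  return out;
}

// Multi-origin mean square displacement of a track.
// [[Rcpp::export]]
NumericMatrix msd_cpp(NumericMatrix x, IntegerVector origins,
                      IntegerVector lags) {
  const int n = x.nrow();
  const int nL = lags.size();
  NumericMatrix out(nL, 2); // msd, n_pairs
  for (int il = 0; il < nL; ++il) {
    const int lag = lags[il];
    double s = 0.0;
    int cnt = 0;
    for (int io = 0; io < origins.size(); ++io) {
      const int t0 = origins[io];
      const int t1 = t0 + lag;
      if (t1 >= n) continue;
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        const double d = x(t1, k) - x(t0, k);
        d2 += d * d;
      }
      s += d2;
      ++cnt;
    }
    out(il, 0) = cnt > 0 ? s / cnt : NA_REAL;
    out(il, 1) = cnt;
  }
  return out;
}
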