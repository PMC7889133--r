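#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed link order throughout: 0 XY, 1 XZ, 2 YY, 3 YZ, 4 ZY, 5 ZZ.
//
// Fold-change dynamics on the unit-basal scale:
//   dY/dt = aY * (F_Y(X, Y, Z) - Y)
//   dZ/dt = aZ * (F_Z(X, Y, Z) - Z)
// where F_T is the product of normalized Hill factors over T's incoming
// nonzero links; the empty product is 1, so an unregulated node rests at 1.
// Activation: h+(u) = u^n (K^n + 1) / (K^n + u^n);  repression:
// h-(u) = (K^n + 1) / (K^n + u^n).  Both equal 1 at u = 1, making the basal
// state (all nodes at 1) an exact fixed point for flat input.

static const double STATE_FLOOR = 1e-9;  // clip below: fold changes stay positive
static const double STATE_CEIL = 1e6;    // beyond this the combo is unusable

static inline double upow(double u, int n) {
  switch (n) {
  case 1: return u;
  case 2: return u * u;
  case 3: return u * u * u;
  case 4: { double s = u * u; return s * s; }
  default: return std::pow(u, (double)n);
  }
}

static inline double hill(double u, double Kn, int n, int sign) {
  double un = upow(u, n);
  if (sign > 0) return un * (Kn + 1.0) / (Kn + un);
  return (Kn + 1.0) / (Kn + un);
}

struct MotifPars {
  int s[6];        // link signs
  double Kn[6];    // K^n per link (only used where s != 0)
  double Kn1[6];   // K^n + 1
  int n[6];
  double aY, aZ;
};

// Product of normalized Hill factors per node, accumulated as one numerator
// and one denominator so each node costs a single division per evaluation.
static inline void hill_accum(double u, double Kn, double Kn1, int n, int sign,
                              double &num, double &den) {
  double un = upow(u, n);
  num *= (sign > 0) ? un * Kn1 : Kn1;
  den *= Kn + un;
}

static inline void deriv(const MotifPars &mp, double x, double y, double z,
                         double &dy, double &dz) {
  double nY = 1.0, dY = 1.0, nZ = 1.0, dZ = 1.0;
  if (mp.s[0]) hill_accum(x, mp.Kn[0], mp.Kn1[0], mp.n[0], mp.s[0], nY, dY);
  if (mp.s[2]) hill_accum(y, mp.Kn[2], mp.Kn1[2], mp.n[2], mp.s[2], nY, dY);
  if (mp.s[4]) hill_accum(z, mp.Kn[4], mp.Kn1[4], mp.n[4], mp.s[4], nY, dY);
  if (mp.s[1]) hill_accum(x, mp.Kn[1], mp.Kn1[1], mp.n[1], mp.s[1], nZ, dZ);
  if (mp.s[3]) hill_accum(y, mp.Kn[3], mp.Kn1[3], mp.n[3], mp.s[3], nZ, dZ);
  if (mp.s[5]) hill_accum(z, mp.Kn[5], mp.Kn1[5], mp.n[5], mp.s[5], nZ, dZ);
  dy = mp.aY * (nY / dY - y);
  dz = mp.aZ * (nZ / dZ - z);
}

// One classic RK4 step of size h; x sampled at t (x0), t+h/2 (xm), t+h (x1).
static inline bool rk4_step(const MotifPars &mp, double h, double x0, double xm,
                            double x1, double &y, double &z) {
  double k1y, k1z, k2y, k2z, k3y, k3z, k4y, k4z;
  deriv(mp, x0, y, z, k1y, k1z);
  deriv(mp, xm, y + 0.5 * h * k1y, z + 0.5 * h * k1z, k2y, k2z);
  deriv(mp, xm, y + 0.5 * h * k2y, z + 0.5 * h * k2z, k3y, k3z);
  deriv(mp, x1, y + h * k3y, z + h * k3z, k4y, k4z);
  y += h / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
  z += h / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
  if (y < STATE_FLOOR) y = STATE_FLOOR;
  if (z < STATE_FLOOR) z = STATE_FLOOR;
  return std::isfinite(y) && std::isfinite(z) && y < STATE_CEIL && z < STATE_CEIL;
}

static void fill_pars(MotifPars &mp, const IntegerVector &signs,
                      const double *K, const int *n, double aY, double aZ) {
  for (int l = 0; l < 6; ++l) {
    mp.s[l] = signs[l];
    mp.n[l] = n[l];
    mp.Kn[l] = upow(K[l], n[l]);
    mp.Kn1[l] = mp.Kn[l] + 1.0;
  }
  mp.aY = aY;
  mp.aZ = aZ;
}

// Integrate one motif for one parameter set across all cells, returning Y and
// Z trajectories at the observation grid points.
//
// xhalf: matrix [(2*refine*(nT-1) + 1) x nCells] of upstream values sampled at
// half-step resolution on the refined grid. tgrid: the nT observation times.
// [[Rcpp::export]]
List rk4_trajectories(IntegerVector signs, NumericMatrix xhalf,
                      NumericVector tgrid, int refine, NumericVector K,
                      IntegerVector n, double aY, double aZ) {
  int nT = tgrid.size(), nC = xhalf.ncol();
  MotifPars mp;
  fill_pars(mp, signs, K.begin(), INTEGER(n), aY, aZ);
  NumericMatrix Y(nT, nC), Z(nT, nC);
  LogicalVector ok(nC, true);
  for (int c = 0; c < nC; ++c) {
    const double *xc = &xhalf(0, c);
    double y = 1.0, z = 1.0;
    Y(0, c) = y; Z(0, c) = z;
    int idx = 0;  // index into xc at half-step resolution
    bool valid = true;
    for (int i = 0; i < nT - 1; ++i) {
      double h = (tgrid[i + 1] - tgrid[i]) / refine;
      for (int r = 0; r < refine; ++r) {
        if (valid &&
            !rk4_step(mp, h, xc[idx], xc[idx + 1], xc[idx + 2], y, z))
          valid = false;
        idx += 2;
      }
      Y(i + 1, c) = y; Z(i + 1, c) = z;
    }
    ok[c] = valid;
  }
  return List::create(_["Y"] = Y, _["Z"] = Z, _["ok"] = ok);
}

// Score one motif against observed Z traces for a whole bank of parameter
// sets.  Returns, per parameter set, the error
//   E = mean over cells of [ trapezoid_t |Z(t) - Z'(t)| / (t_end - t_0) ]
// evaluated on the observation grid, plus a validity flag (FALSE when any
// cell's trajectory left the representable range).
//
// Kmat [nP x 6], nmat [nP x 6], aY/aZ length nP; zobs [nT x nCells].
// [[Rcpp::export]]
List rk4_score(IntegerVector signs, NumericMatrix xhalf, NumericMatrix zobs,
               NumericVector tgrid, int refine, NumericMatrix Kmat,
               IntegerMatrix nmat, NumericVector aY, NumericVector aZ) {
  int nT = tgrid.size(), nC = xhalf.ncol(), nP = Kmat.nrow();
  double duration = tgrid[nT - 1] - tgrid[0];
  NumericVector err(nP);
  LogicalVector valid(nP, true);

  // precompute trapezoid weights on the observation grid
  std::vector<double> w(nT, 0.0);
  for (int i = 0; i < nT - 1; ++i) {
    double dt = tgrid[i + 1] - tgrid[i];
    w[i] += 0.5 * dt;
    w[i + 1] += 0.5 * dt;
  }

  MotifPars mp;
  for (int l = 0; l < 6; ++l) mp.s[l] = signs[l];

  for (int p = 0; p < nP; ++p) {
    for (int l = 0; l < 6; ++l) {
      mp.n[l] = nmat(p, l);
      mp.Kn[l] = mp.s[l] ? upow(Kmat(p, l), mp.n[l]) : 1.0;
      mp.Kn1[l] = mp.Kn[l] + 1.0;
    }
    mp.aY = aY[p];
    mp.aZ = aZ[p];

    double acc = 0.0;
    bool ok = true;
    for (int c = 0; c < nC && ok; ++c) {
      const double *xc = &xhalf(0, c);
      const double *zc = &zobs(0, c);
      double y = 1.0, z = 1.0;
      double cell = w[0] * std::fabs(zc[0] - z);
      int idx = 0;
      for (int i = 0; i < nT - 1; ++i) {
        double h = (tgrid[i + 1] - tgrid[i]) / refine;
        for (int r = 0; r < refine; ++r) {
          if (!rk4_step(mp, h, xc[idx], xc[idx + 1], xc[idx + 2], y, z)) {
            ok = false;
            break;
          }
          idx += 2;
        }
        if (!ok) break;
        cell += w[i + 1] * std::fabs(zc[i + 1] - z);
      }
      acc += cell;
    }
    if (ok) {
      // mean over cells of the duration-normalized integral, associated as
      // in the R-side error_score so the two paths agree to rounding
      err[p] = acc / nC / duration;
    } else {
      err[p] = NA_REAL;
      valid[p] = false;
    }
  }
  return List::create(_["error"] = err, _["valid"] = valid);
}
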