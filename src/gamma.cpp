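#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Gamma-index search over a precomputed displacement list (mm offsets sorted
// by increasing norm, (0,0,0) first). For each above-threshold reference
// voxel the scan stops once offset_norm/dta >= current best gamma: the
// distance term alone then dominates, so the result equals the full scan.
// Evaluated dose is sampled with trilinear interpolation; offsets whose
// sample point falls outside the evaluated grid are skipped.

static double tri_eval(const double *v, int nx, int ny, int nz,
                       double cx, double cy, double cz, bool &ok) {
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5) { ok = false; return 0.0; }
  ok = true;
  double x = std::min(std::max(cx, 0.0), nx - 1.0);
  double y = std::min(std::max(cy, 0.0), ny - 1.0);
  double z = std::min(std::max(cz, 0.0), nz - 1.0);
  int i0 = std::min(std::max((int)std::floor(x), 0), std::max(nx - 2, 0));
  int j0 = std::min(std::max((int)std::floor(y), 0), std::max(ny - 2, 0));
  int k0 = std::min(std::max((int)std::floor(z), 0), std::max(nz - 2, 0));
  int i1 = (nx > 1) ? i0 + 1 : i0, j1 = (ny > 1) ? j0 + 1 : j0, k1 = (nz > 1) ? k0 + 1 : k0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  size_t sxy = (size_t)nx * ny;
  #define V(i,j,k) v[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
  double c00 = V(i0,j0,k0) * (1-fx) + V(i1,j0,k0) * fx;
  double c10 = V(i0,j1,k0) * (1-fx) + V(i1,j1,k0) * fx;
  double c01 = V(i0,j0,k1) * (1-fx) + V(i1,j0,k1) * fx;
  double c11 = V(i0,j1,k1) * (1-fx) + V(i1,j1,k1) * fx;
  #undef V
  return (c00 * (1-fy) + c10 * fy) * (1-fz) + (c01 * (1-fy) + c11 * fy) * fz;
}

// [[Rcpp::export]]
NumericVector gamma_search_cpp(NumericVector ref, IntegerVector rdim,
                               NumericVector rspac, NumericVector rorig,
                               NumericVector ev, IntegerVector edim,
                               NumericVector espac, NumericVector eorig,
                               double dd_abs, double dta, double thr_abs,
                               NumericMatrix offsets) {
  int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  int ex = edim[0], ey = edim[1], ez = edim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  int noff = offsets.nrow();
  std::vector<double> ox(noff), oy(noff), oz(noff), onorm(noff);
  for (int t = 0; t < noff; ++t) {
    ox[t] = offsets(t,0); oy[t] = offsets(t,1); oz[t] = offsets(t,2);
    onorm[t] = std::sqrt(ox[t]*ox[t] + oy[t]*oy[t] + oz[t]*oz[t]);
  }
  const double *e = ev.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double dr = ref[idx];
        if (!(dr >= thr_abs)) continue;
        double wx = rorig[0] + (i + 0.5) * rspac[0];
        double wy = rorig[1] + (j + 0.5) * rspac[1];
        double wz = rorig[2] + (k + 0.5) * rspac[2];
        double best = R_PosInf;
        for (int t = 0; t < noff; ++t) {
          double dterm = onorm[t] / dta;
          if (dterm >= best) break; // offsets sorted by norm: exact stop
          double cx = (wx + ox[t] - eorig[0]) / espac[0] - 0.5;
          double cy = (wy + oy[t] - eorig[1]) / espac[1] - 0.5;
          double cz = (wz + oz[t] - eorig[2]) / espac[2] - 0.5;
          bool ok;
          double de = tri_eval(e, ex, ey, ez, cx, cy, cz, ok);
          if (!ok) continue;
          double dd = (de - dr) / dd_abs;
          double g = std::sqrt(dterm * dterm + dd * dd);
          if (g < best) best = g;
        }
        out[idx] = best;
      }
  return out;
}

// Independent brute-force oracle: dense displacement lattice at a fine step,
// scanned shell-by-shell of increasing radius. Scanning stops only when the
// shell radius alone guarantees no improvement (exact dominance), so the
// result equals the complete dense scan within its step size. Written as a
// separate code path from gamma_search_cpp on purpose.
// [[Rcpp::export]]
NumericVector gamma_brute_cpp(NumericVector ref, IntegerVector rdim,
                              NumericVector rspac, NumericVector rorig,
                              NumericVector ev, IntegerVector edim,
                              NumericVector espac, NumericVector eorig,
                              double dd_abs, double dta, double thr_abs,
                              double step, double radius_cap) {
  int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  int ex = edim[0], ey = edim[1], ez = edim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  int rmax = (int)std::floor(radius_cap / step + 1e-9);
  // group lattice offsets into integer-radius shells
  struct Off { double x, y, z, norm; };
  std::vector<std::vector<Off>> shells;
  for (int a = -rmax; a <= rmax; ++a)
    for (int b = -rmax; b <= rmax; ++b)
      for (int c = -rmax; c <= rmax; ++c) {
        double nr = std::sqrt((double)a*a + b*b + c*c) * step;
        if (nr > radius_cap + 1e-12) continue;
        int shell = (int)std::floor(nr / step + 1e-9);
        if ((int)shells.size() <= shell) shells.resize(shell + 1);
        shells[shell].push_back({a * step, b * step, c * step, nr});
      }
  const double *e = ev.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double dr = ref[idx];
        if (!(dr >= thr_abs)) continue;
        double wx = rorig[0] + (i + 0.5) * rspac[0];
        double wy = rorig[1] + (j + 0.5) * rspac[1];
        double wz = rorig[2] + (k + 0.5) * rspac[2];
        double best = R_PosInf;
        for (size_t s = 0; s < shells.size(); ++s) {
          double shell_min_norm = s * step;
          if (shell_min_norm / dta >= best) break; // exact dominance
          for (const Off &o : shells[s]) {
            double cx = (wx + o.x - eorig[0]) / espac[0] - 0.5;
            double cy = (wy + o.y - eorig[1]) / espac[1] - 0.5;
            double cz = (wz + o.z - eorig[2]) / espac[2] - 0.5;
            bool ok;
            double de = tri_eval(e, ex, ey, ez, cx, cy, cz, ok);
            if (!ok) continue;
            double dd = (de - dr) / dd_abs;
            double dt = o.norm / dta;
            double g = std::sqrt(dt * dt + dd * dd);
            if (g < best) best = g;
          }
        }
        out[idx] = best;
      }
  return out;
}
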