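#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact voxel traversal (Siddon / Amanatides-Woo). Grid box spans
// [orig, orig + dim*spac] in world mm; voxel (i,j,k) covers
// [orig + i*spac, orig + (i+1)*spac).

struct Ray {
  double p0[3], d[3]; // origin, unit direction
};

static bool box_clip(const Ray &r, const double lo[3], const double hi[3],
                     double &t0, double &t1) {
  t0 = 0.0; t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(r.d[a]) < 1e-12) {
      if (r.p0[a] < lo[a] || r.p0[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - r.p0[a]) / r.d[a];
      double tb = (hi[a] - r.p0[a]) / r.d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  return t0 < t1;
}

// Trace one ray through the whole grid; returns per-crossed-voxel indices
// (0-based), intersection lengths, densities and the cumulative
// water-equivalent depth at each segment's exit.
// [[Rcpp::export]]
List siddon_trace_cpp(NumericVector dens, IntegerVector dim,
                      NumericVector spac, NumericVector orig,
                      NumericVector p0, NumericVector dir) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Ray r;
  double nrm = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  for (int a = 0; a < 3; ++a) { r.p0[a] = p0[a]; r.d[a] = dir[a] / nrm; }
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = orig[a]; hi[a] = orig[a] + dim[a] * spac[a]; }
  double t0, t1;
  std::vector<int> vi, vj, vk;
  std::vector<double> len, dn, wed;
  if (box_clip(r, lo, hi, t0, t1)) {
    t0 = std::max(t0, 0.0);
    if (t1 > t0) {
      // current voxel at entry (nudge inside)
      double t = t0, eps = 1e-9 * (t1 - t0 + 1.0);
      int idx[3];
      for (int a = 0; a < 3; ++a) {
        double w = r.p0[a] + (t0 + eps) * r.d[a];
        int q = (int)std::floor((w - orig[a]) / spac[a]);
        idx[a] = std::min(std::max(q, 0), dim[a] - 1);
      }
      int stepv[3]; double tDelta[3], tMax[3];
      for (int a = 0; a < 3; ++a) {
        if (r.d[a] > 1e-12) {
          stepv[a] = 1;
          tDelta[a] = spac[a] / r.d[a];
          tMax[a] = ((orig[a] + (idx[a] + 1) * spac[a]) - r.p0[a]) / r.d[a];
        } else if (r.d[a] < -1e-12) {
          stepv[a] = -1;
          tDelta[a] = -spac[a] / r.d[a];
          tMax[a] = ((orig[a] + idx[a] * spac[a]) - r.p0[a]) / r.d[a];
        } else {
          stepv[a] = 0;
          tDelta[a] = std::numeric_limits<double>::infinity();
          tMax[a] = std::numeric_limits<double>::infinity();
        }
      }
      double acc = 0;
      size_t sxy = (size_t)nx * ny;
      while (t < t1 - 1e-12) {
        int a = 0;
        if (tMax[1] < tMax[a]) a = 1;
        if (tMax[2] < tMax[a]) a = 2;
        double tn = std::min(tMax[a], t1);
        double L = tn - t;
        if (L > 0) {
          double d = dens[(size_t)idx[0] + (size_t)nx * idx[1] + sxy * idx[2]];
          acc += L * d;
          vi.push_back(idx[0]); vj.push_back(idx[1]); vk.push_back(idx[2]);
          len.push_back(L); dn.push_back(d); wed.push_back(acc);
        }
        t = tn;
        if (tMax[a] >= t1) break;
        idx[a] += stepv[a];
        if (idx[a] < 0 || idx[a] >= dim[a]) break;
        tMax[a] += tDelta[a];
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["k"] = wrap(vk),
                      _["length"] = wrap(len), _["density"] = wrap(dn),
                      _["wed"] = wrap(wed));
}

// Water-equivalent depth from grid entry to a world point along a ray from
// `src` (divergent) or along fixed direction `dir` (parallel).
static double wed_to_point(const double *dens, const int *dim,
                           const double *spac, const double *orig,
                           const double from[3], const double to[3]) {
  Ray r;
  double d[3], nrm = 0;
  for (int a = 0; a < 3; ++a) { d[a] = to[a] - from[a]; nrm += d[a]*d[a]; }
  nrm = std::sqrt(nrm);
  if (nrm < 1e-12) return 0.0;
  for (int a = 0; a < 3; ++a) { r.p0[a] = from[a]; r.d[a] = d[a] / nrm; }
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = orig[a]; hi[a] = orig[a] + dim[a] * spac[a]; }
  double t0, t1;
  if (!box_clip(r, lo, hi, t0, t1)) return 0.0;
  t0 = std::max(t0, 0.0);
  double tEnd = std::min(nrm, t1);
  if (tEnd <= t0) return 0.0;
  int idx[3];
  double eps = 1e-9 * (tEnd - t0 + 1.0);
  for (int a = 0; a < 3; ++a) {
    double w = r.p0[a] + (t0 + eps) * r.d[a];
    int q = (int)std::floor((w - orig[a]) / spac[a]);
    idx[a] = std::min(std::max(q, 0), dim[a] - 1);
  }
  int stepv[3]; double tDelta[3], tMax[3];
  for (int a = 0; a < 3; ++a) {
    if (r.d[a] > 1e-12) {
      stepv[a] = 1;
      tDelta[a] = spac[a] / r.d[a];
      tMax[a] = ((orig[a] + (idx[a] + 1) * spac[a]) - r.p0[a]) / r.d[a];
    } else if (r.d[a] < -1e-12) {
      stepv[a] = -1;
      tDelta[a] = -spac[a] / r.d[a];
      tMax[a] = ((orig[a] + idx[a] * spac[a]) - r.p0[a]) / r.d[a];
    } else {
      stepv[a] = 0;
      tDelta[a] = tMax[a] = std::numeric_limits<double>::infinity();
    }
  }
  double t = t0, acc = 0;
  size_t nx = dim[0];
  size_t sxy = (size_t)dim[0] * dim[1];
  while (t < tEnd - 1e-12) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tn = std::min(tMax[a], tEnd);
    acc += (tn - t) * dens[(size_t)idx[0] + nx * idx[1] + sxy * idx[2]];
    t = tn;
    if (tMax[a] >= tEnd) break;
    idx[a] += stepv[a];
    if (idx[a] < 0 || idx[a] >= dim[a]) break;
    tMax[a] += tDelta[a];
  }
  return acc;
}

// Exact per-voxel water-equivalent depth (one Siddon trace per voxel).
// [[Rcpp::export]]
NumericVector wed_siddon_cpp(NumericVector dens, IntegerVector dim,
                             NumericVector spac, NumericVector orig,
                             NumericVector src, NumericVector dir,
                             bool parallel) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double diag = 0;
  for (int a = 0; a < 3; ++a) diag += dim[a] * spac[a] * dim[a] * spac[a];
  double far = 2.0 * std::sqrt(diag) + 10.0;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double to[3] = {orig[0] + (i + 0.5) * spac[0],
                        orig[1] + (j + 0.5) * spac[1],
                        orig[2] + (k + 0.5) * spac[2]};
        double from[3];
        if (parallel) {
          double nrm = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
          for (int a = 0; a < 3; ++a) from[a] = to[a] - far * dir[a] / nrm;
        } else {
          for (int a = 0; a < 3; ++a) from[a] = src[a];
        }
        out[idx] = wed_to_point(dens.begin(), dim.begin(), spac.begin(),
                                orig.begin(), from, to);
      }
  return out;
}

static double tri3(const double *v, int nx, int ny, int nz,
                   double cx, double cy, double cz) {
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5)
    return 0.0;
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

// Incremental plane-sweep water-equivalent depth: one grid plane per step
// along the beam's major axis, trapezoidal density and a trilinear lookback
// into the depth planes already computed. O(nvox) per beam.
// [[Rcpp::export]]
NumericVector wed_sweep_cpp(NumericVector dens, IntegerVector dim,
                            NumericVector spac, NumericVector orig,
                            NumericVector src, NumericVector dir,
                            bool parallel) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  double dn = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  double d0[3] = {dir[0]/dn, dir[1]/dn, dir[2]/dn};
  int m = 0;
  if (std::fabs(d0[1]) > std::fabs(d0[m])) m = 1;
  if (std::fabs(d0[2]) > std::fabs(d0[m])) m = 2;
  int nm = dim[m];
  int pstart = d0[m] > 0 ? 0 : nm - 1;
  int pstep = d0[m] > 0 ? 1 : -1;
  const double *rho = dens.begin();
  double *w = out.begin();
  size_t sxy = (size_t)nx * ny;
  for (int pc = 0; pc < nm; ++pc) {
    int p = pstart + pc * pstep;
    int i0 = 0, i1 = nx, j0 = 0, j1 = ny, k0 = 0, k1 = nz;
    if (m == 0) { i0 = p; i1 = p + 1; }
    if (m == 1) { j0 = p; j1 = p + 1; }
    if (m == 2) { k0 = p; k1 = p + 1; }
    for (int k = k0; k < k1; ++k)
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) {
          size_t idx = (size_t)i + (size_t)nx * j + sxy * k;
          double x[3] = {orig[0] + (i + 0.5) * spac[0],
                         orig[1] + (j + 0.5) * spac[1],
                         orig[2] + (k + 0.5) * spac[2]};
          double u[3];
          if (parallel) { u[0] = d0[0]; u[1] = d0[1]; u[2] = d0[2]; }
          else {
            double s = 0;
            for (int a = 0; a < 3; ++a) { u[a] = x[a] - src[a]; s += u[a]*u[a]; }
            s = std::sqrt(s);
            for (int a = 0; a < 3; ++a) u[a] /= s;
          }
          double um = std::fabs(u[m]) < 0.2 ? (u[m] < 0 ? -0.2 : 0.2) : u[m];
          double scale = spac[m] / std::fabs(um);
          double rh = rho[idx];
          if (pc == 0) {
            w[idx] = rh * 0.5 * scale;
          } else {
            double prev[3], cp[3];
            for (int a = 0; a < 3; ++a) prev[a] = x[a] - u[a] * scale;
            for (int a = 0; a < 3; ++a) cp[a] = (prev[a] - orig[a]) / spac[a] - 0.5;
            double wprev = tri3(w, nx, ny, nz, cp[0], cp[1], cp[2]);
            double rprev = tri3(rho, nx, ny, nz, cp[0], cp[1], cp[2]);
            w[idx] = wprev + 0.5 * (rh + rprev) * scale;
          }
        }
  }
  return out;
}
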