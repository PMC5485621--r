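#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel-center convention used everywhere: world = origin + (index + 0.5) * spacing
// with 0-based indices; continuous index c = (world - origin)/spacing - 0.5.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sample at continuous 0-based index. Outside the half-voxel border
// returns `fill`; inside the border values are clamped to the edge.
static double tri_sample(const double *v, int nx, int ny, int nz,
                         double cx, double cy, double cz, double fill) {
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5)
    return fill;
  double x = clampd(cx, 0.0, nx - 1.0);
  double y = clampd(cy, 0.0, ny - 1.0);
  double z = clampd(cz, 0.0, nz - 1.0);
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  int i1 = (nx > 1) ? i0 + 1 : i0;
  int j1 = (ny > 1) ? j0 + 1 : j0;
  int k1 = (nz > 1) ? k0 + 1 : k0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  size_t sxy = (size_t)nx * ny;
  #define V(i,j,k) v[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
  double c00 = V(i0,j0,k0) * (1-fx) + V(i1,j0,k0) * fx;
  double c10 = V(i0,j1,k0) * (1-fx) + V(i1,j1,k0) * fx;
  double c01 = V(i0,j0,k1) * (1-fx) + V(i1,j0,k1) * fx;
  double c11 = V(i0,j1,k1) * (1-fx) + V(i1,j1,k1) * fx;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

static double nn_sample(const double *v, int nx, int ny, int nz,
                        double cx, double cy, double cz, double fill) {
  if (cx < -0.5 || cy < -0.5 || cz < -0.5 ||
      cx > nx - 0.5 || cy > ny - 0.5 || cz > nz - 0.5)
    return fill;
  int i = (int)std::lround(clampd(cx, 0.0, nx - 1.0));
  int j = (int)std::lround(clampd(cy, 0.0, ny - 1.0));
  int k = (int)std::lround(clampd(cz, 0.0, nz - 1.0));
  return v[(size_t)i + (size_t)nx * j + (size_t)nx * ny * k];
}

// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector src, IntegerVector sdim,
                                NumericVector sspac, NumericVector sorig,
                                IntegerVector tdim, NumericVector tspac,
                                NumericVector torig, bool nearest, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int mx = tdim[0], my = tdim[1], mz = tdim[2];
  NumericVector out((size_t)mx * my * mz);
  const double *v = src.begin();
  size_t idx = 0;
  for (int k = 0; k < mz; ++k) {
    double wz = torig[2] + (k + 0.5) * tspac[2];
    double cz = (wz - sorig[2]) / sspac[2] - 0.5;
    for (int j = 0; j < my; ++j) {
      double wy = torig[1] + (j + 0.5) * tspac[1];
      double cy = (wy - sorig[1]) / sspac[1] - 0.5;
      for (int i = 0; i < mx; ++i, ++idx) {
        double wx = torig[0] + (i + 0.5) * tspac[0];
        double cx = (wx - sorig[0]) / sspac[0] - 0.5;
        out[idx] = nearest ? nn_sample(v, nx, ny, nz, cx, cy, cz, fill)
                           : tri_sample(v, nx, ny, nz, cx, cy, cz, fill);
      }
    }
  }
  return out;
}

// Pull-back warp: out(x) = src(x + u(x)), u in mm on the target grid.
// [[Rcpp::export]]
NumericVector warp_field_cpp(NumericVector src, IntegerVector sdim,
                             NumericVector sspac, NumericVector sorig,
                             NumericVector ux, NumericVector uy, NumericVector uz,
                             IntegerVector tdim, NumericVector tspac,
                             NumericVector torig, bool nearest, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int mx = tdim[0], my = tdim[1], mz = tdim[2];
  NumericVector out((size_t)mx * my * mz);
  const double *v = src.begin();
  size_t idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx) {
        double wx = torig[0] + (i + 0.5) * tspac[0] + ux[idx];
        double wy = torig[1] + (j + 0.5) * tspac[1] + uy[idx];
        double wz = torig[2] + (k + 0.5) * tspac[2] + uz[idx];
        double cx = (wx - sorig[0]) / sspac[0] - 0.5;
        double cy = (wy - sorig[1]) / sspac[1] - 0.5;
        double cz = (wz - sorig[2]) / sspac[2] - 0.5;
        out[idx] = nearest ? nn_sample(v, nx, ny, nz, cx, cy, cz, fill)
                           : tri_sample(v, nx, ny, nz, cx, cy, cz, fill);
      }
  return out;
}

// Affine pull-back: out(x) = src(A x) for 4x4 affine A on world coordinates.
// [[Rcpp::export]]
NumericVector affine_warp_cpp(NumericVector src, IntegerVector sdim,
                              NumericVector sspac, NumericVector sorig,
                              NumericMatrix A, IntegerVector tdim,
                              NumericVector tspac, NumericVector torig,
                              bool nearest, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int mx = tdim[0], my = tdim[1], mz = tdim[2];
  NumericVector out((size_t)mx * my * mz);
  const double *v = src.begin();
  size_t idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx) {
        double wx = torig[0] + (i + 0.5) * tspac[0];
        double wy = torig[1] + (j + 0.5) * tspac[1];
        double wz = torig[2] + (k + 0.5) * tspac[2];
        double px = A(0,0)*wx + A(0,1)*wy + A(0,2)*wz + A(0,3);
        double py = A(1,0)*wx + A(1,1)*wy + A(1,2)*wz + A(1,3);
        double pz = A(2,0)*wx + A(2,1)*wy + A(2,2)*wz + A(2,3);
        double cx = (px - sorig[0]) / sspac[0] - 0.5;
        double cy = (py - sorig[1]) / sspac[1] - 0.5;
        double cz = (pz - sorig[2]) / sspac[2] - 0.5;
        out[idx] = nearest ? nn_sample(v, nx, ny, nz, cx, cy, cz, fill)
                           : tri_sample(v, nx, ny, nz, cx, cy, cz, fill);
      }
  return out;
}

// Trilinear sample at arbitrary world points.
// [[Rcpp::export]]
NumericVector sample_points_cpp(NumericVector src, IntegerVector sdim,
                                NumericVector sspac, NumericVector sorig,
                                NumericMatrix pts, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = src.begin();
  for (int r = 0; r < n; ++r) {
    double cx = (pts(r,0) - sorig[0]) / sspac[0] - 0.5;
    double cy = (pts(r,1) - sorig[1]) / sspac[1] - 0.5;
    double cz = (pts(r,2) - sorig[2]) / sspac[2] - 0.5;
    out[r] = tri_sample(v, nx, ny, nz, cx, cy, cz, fill);
  }
  return out;
}

// Separable Gaussian smoothing, sigma in voxels per axis, kernel radius 3 sigma.
// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector src, IntegerVector dim,
                               NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> buf(src.begin(), src.end()), tmp(n);
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += ker[t + r]; }
    for (double &kv : ker) kv /= sum;
    int stride = strides[ax], len = sizes[ax];
    // iterate over all lines along axis ax
    for (int k = 0; k < (ax == 2 ? 1 : nz); ++k)
      for (int j = 0; j < (ax == 1 ? 1 : ny); ++j)
        for (int i = 0; i < (ax == 0 ? 1 : nx); ++i) {
          size_t base = (size_t)i * 1 + (size_t)j * nx + (size_t)k * nx * ny;
          for (int p = 0; p < len; ++p) {
            double acc = 0;
            for (int t = -r; t <= r; ++t) {
              int q = p + t;
              if (q < 0) q = 0;
              if (q >= len) q = len - 1;
              acc += ker[t + r] * buf[base + (size_t)q * stride];
            }
            tmp[base + (size_t)p * stride] = acc;
          }
        }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Central-difference gradient, per-mm units.
// [[Rcpp::export]]
List gradient_cpp(NumericVector src, IntegerVector dim, NumericVector spac) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector gx(n), gy(n), gz(n);
  const double *v = src.begin();
  size_t sxy = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        gx[idx] = (v[(size_t)ip + (size_t)nx*j + sxy*k] - v[(size_t)im + (size_t)nx*j + sxy*k]) / ((ip - im) * spac[0]);
        gy[idx] = (v[(size_t)i + (size_t)nx*jp + sxy*k] - v[(size_t)i + (size_t)nx*jm + sxy*k]) / ((jp - jm) * spac[1]);
        gz[idx] = (v[(size_t)i + (size_t)nx*j + sxy*kp] - v[(size_t)i + (size_t)nx*j + sxy*km]) / ((kp - km) * spac[2]);
      }
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}

// 6-connected component labelling of a binary mask; labels 1..ncomp by BFS order.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
      const int di[6] = {-1,1,0,0,0,0}, dj[6] = {0,0,-1,1,0,0}, dk[6] = {0,0,0,0,-1,1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t q = (size_t)ii + (size_t)nx * jj + (size_t)nx * ny * kk;
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Fill interior holes: background voxels not 6-connected to the volume border
// become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1) continue;
        size_t p = (size_t)i + (size_t)nx * j + (size_t)nx * ny * k;
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  while (!stack.empty()) {
    size_t p = stack.back(); stack.pop_back();
    int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
    const int di[6] = {-1,1,0,0,0,0}, dj[6] = {0,0,-1,1,0,0}, dk[6] = {0,0,0,0,-1,1};
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      size_t q = (size_t)ii + (size_t)nx * jj + (size_t)nx * ny * kk;
      if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (size_t p = 0; p < n; ++p) out[p] = mask[p] || !outside[p];
  return out;
}
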