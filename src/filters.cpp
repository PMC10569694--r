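#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Arrays are stored in R's column-major order with dim = (nz, ny, nx):
// linear index = z + nz*y + nz*ny*x. Axis 0 = z (fastest), 1 = y, 2 = x.

static inline int reflect_idx(int i, int n) {
  // symmetric boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector conv_axis3d(NumericVector vol, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t plane = (R_xlen_t)n0 * n1;
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(vol.size());
  int len;
  R_xlen_t stride;
  if (axis == 0)      { len = n0; stride = 1; }
  else if (axis == 1) { len = n1; stride = n0; }
  else                { len = n2; stride = plane; }

  std::vector<double> line(len);
  // iterate over all lines along `axis`
  int outerA, outerB;
  if (axis == 0)      { outerA = n1; outerB = n2; }
  else if (axis == 1) { outerA = n0; outerB = n2; }
  else                { outerA = n0; outerB = n1; }

  for (int b = 0; b < outerB; ++b) {
    for (int a = 0; a < outerA; ++a) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)n0 * a + plane * b;
      else if (axis == 1) base = (R_xlen_t)a + plane * b;
      else                base = (R_xlen_t)a + (R_xlen_t)n0 * b;
      for (int i = 0; i < len; ++i) line[i] = vol[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int j = 0; j < klen; ++j)
          acc += kernel[j] * line[reflect_idx(i + j - r, len)];
        out[base + stride * i] = acc;
      }
    }
  }
  return out;
}

// Trilinear / nearest-neighbour sampling at fractional voxel coordinates.
// zyx: n x 3 matrix of 0-based voxel coordinates. Out-of-grid -> fill.
// [[Rcpp::export]]
NumericVector interp3d(NumericVector vol, IntegerVector dim,
                       NumericMatrix zyx, bool nearest, double fill) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t plane = (R_xlen_t)n0 * n1;
  const R_xlen_t n = zyx.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = zyx(i, 0), y = zyx(i, 1), x = zyx(i, 2);
    if (!R_finite(z) || !R_finite(y) || !R_finite(x)) { out[i] = fill; continue; }
    if (nearest) {
      long zi = (long)std::lround(z), yi = (long)std::lround(y), xi = (long)std::lround(x);
      if (zi < 0 || zi >= n0 || yi < 0 || yi >= n1 || xi < 0 || xi >= n2) {
        out[i] = fill;
      } else {
        out[i] = vol[zi + (R_xlen_t)n0 * yi + plane * xi];
      }
    } else {
      if (z < 0 || z > n0 - 1 || y < 0 || y > n1 - 1 || x < 0 || x > n2 - 1) {
        out[i] = fill; continue;
      }
      int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
      int z1 = std::min(z0 + 1, n0 - 1);
      int y1 = std::min(y0 + 1, n1 - 1);
      int x1 = std::min(x0 + 1, n2 - 1);
      double fz = z - z0, fy = y - y0, fx = x - x0;
      double v = 0.0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
            if (w == 0) continue;
            R_xlen_t idx = (dz ? z1 : z0) + (R_xlen_t)n0 * (dy ? y1 : y0) +
                           plane * (dx ? x1 : x0);
            v += w * vol[idx];
          }
      out[i] = v;
    }
  }
  return out;
}

// Sorted eigenvalues (ascending) of per-voxel symmetric 3x3 Hessians given the
// six unique components. Closed-form trigonometric method.
// [[Rcpp::export]]
NumericMatrix sym3_eigenvalues(NumericVector hzz, NumericVector hyy,
                               NumericVector hxx, NumericVector hzy,
                               NumericVector hzx, NumericVector hyx) {
  const R_xlen_t n = hzz.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = hzz[i], b = hyy[i], c = hxx[i];
    double d = hzy[i], e = hzx[i], f = hyx[i];
    double p1 = d * d + e * e + f * f;
    double e1, e2, e3;
    if (p1 == 0.0) {
      e1 = a; e2 = b; e3 = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // B = (A - qI)/p ; r = det(B)/2
      double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      double b12 = d / p, b13 = e / p, b23 = f / p;
      double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double rr = detB / 2.0;
      if (rr < -1.0) rr = -1.0;
      if (rr > 1.0) rr = 1.0;
      double phi = std::acos(rr) / 3.0;
      double emax = q + 2.0 * p * std::cos(phi);
      double emin = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e1 = emin; e3 = emax; e2 = (a + b + c) - emin - emax;
    }
    // sort ascending
    if (e1 > e2) std::swap(e1, e2);
    if (e2 > e3) std::swap(e2, e3);
    if (e1 > e2) std::swap(e1, e2);
    out(i, 0) = e1; out(i, 1) = e2; out(i, 2) = e3;
  }
  return out;
}
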