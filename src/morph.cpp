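#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// dim = (nz, ny, nx); linear index = z + nz*y + nz*ny*x.

static void neighbour_offsets(int connectivity, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int nn = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && nn != 1) continue;
        off.push_back({dz, dy, dx});
      }
}

// Connected-component labeling of a binary grid; labels 1..K in scan order.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t plane = (R_xlen_t)n0 * n1;
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % n0);
      int y = (int)((cur / n0) % n1);
      int x = (int)(cur / plane);
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 || xx < 0 || xx >= n2) continue;
        R_xlen_t ni = zz + (R_xlen_t)n0 * yy + plane * xx;
        if (mask[ni] && lab[ni] == 0) { lab[ni] = next; stack.push_back(ni); }
      }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) on samples at
// positions i*w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * w;
    double s;
    while (true) {
      double vs = v[k] * w;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * w;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * w;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: distance (in physical units) from
// each foreground voxel to the nearest background voxel center. 0 on background.
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t plane = (R_xlen_t)n0 * n1;
  const R_xlen_t n = mask.size();
  const double INF = 1e30;
  std::vector<double> d2(n);
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = mask[i] ? INF : 0.0;

  int maxlen = std::max(n0, std::max(n1, n2));
  std::vector<double> f(maxlen), d(maxlen), z(maxlen + 1);
  std::vector<int> v(maxlen);

  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    int len;
    R_xlen_t stride;
    int outerA, outerB;
    double w = spacing[axis];
    if (axis == 0)      { len = n0; stride = 1;     outerA = n1; outerB = n2; }
    else if (axis == 1) { len = n1; stride = n0;    outerA = n0; outerB = n2; }
    else                { len = n2; stride = plane; outerA = n0; outerB = n1; }
    for (int b = 0; b < outerB; ++b) {
      for (int a = 0; a < outerA; ++a) {
        R_xlen_t base;
        if (axis == 0)      base = (R_xlen_t)n0 * a + plane * b;
        else if (axis == 1) base = (R_xlen_t)a + plane * b;
        else                base = (R_xlen_t)a + (R_xlen_t)n0 * b;
        for (int i = 0; i < len; ++i) f[i] = d2[base + stride * i];
        dt1d(f, d, v, z, len, w);
        for (int i = 0; i < len; ++i) d2[base + stride * i] = d[i];
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(std::min(d2[i], 1e30));
  return out;
}

struct QItem {
  double prio;
  R_xlen_t order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio; // min-heap on priority
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Meyer-style flooding watershed with dams. `prio` is the topographic height
// (flood from low to high; pass the negated distance transform). Seed voxels
// carry positive labels; output: basin labels, dams = -1, background = 0.
// [[Rcpp::export]]
IntegerVector watershed3d(NumericVector prio, LogicalVector mask,
                          IntegerVector seeds, IntegerVector dim,
                          int connectivity) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t plane = (R_xlen_t)n0 * n1;
  const R_xlen_t n = mask.size();
  IntegerVector lab = clone(seeds);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  R_xlen_t counter = 0;

  // push unlabeled mask voxels adjacent to a seed
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    int z = (int)(s % n0), y = (int)((s / n0) % n1), x = (int)(s / plane);
    bool adj = false;
    for (size_t k = 0; k < off.size() && !adj; ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 || xx < 0 || xx >= n2) continue;
      if (lab[zz + (R_xlen_t)n0 * yy + plane * xx] > 0) adj = true;
    }
    if (adj) pq.push({prio[s], counter++, s});
  }

  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    R_xlen_t s = it.idx;
    if (lab[s] != 0) continue;
    int z = (int)(s % n0), y = (int)((s / n0) % n1), x = (int)(s / plane);
    int found = 0, l1 = 0;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 || xx < 0 || xx >= n2) continue;
      int ln = lab[zz + (R_xlen_t)n0 * yy + plane * xx];
      if (ln > 0) {
        if (found == 0) { l1 = ln; found = 1; }
        else if (ln != l1) { found = 2; break; }
      }
    }
    if (found >= 2) {
      lab[s] = -1; // dam
    } else if (found == 1) {
      lab[s] = l1;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= n0 || yy < 0 || yy >= n1 || xx < 0 || xx >= n2) continue;
        R_xlen_t ni = zz + (R_xlen_t)n0 * yy + plane * xx;
        if (mask[ni] && lab[ni] == 0) pq.push({prio[ni], counter++, ni});
      }
    }
    // found == 0 cannot happen: voxels are only queued next to a labeled voxel
  }
  return lab;
}
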