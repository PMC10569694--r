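#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Classification random forest (binary, Gini impurity, bootstrap, feature
// subsampling) sized for sparse-annotation training sets (tens to thousands
// of voxels). Trees are returned as plain numeric matrices so a saved model
// is a transparent, text-serializable object:
//   columns: feature (0-based, -1 = leaf), threshold, left, right, prob
// Randomness comes from R's RNG so set.seed() on the R side makes training
// fully reproducible.

struct TreeNodes {
  std::vector<double> feat, thr, left, right, prob;
  int add() {
    feat.push_back(-1); thr.push_back(0); left.push_back(-1);
    right.push_back(-1); prob.push_back(0);
    return (int)feat.size() - 1;
  }
};

static void build_node(const NumericMatrix &X, const IntegerVector &y,
                       std::vector<int> &idx, int lo, int hi, int node,
                       TreeNodes &T, int mtry, std::vector<int> &featpool,
                       std::vector<std::pair<double,int>> &buf) {
  const int n = hi - lo;
  int npos = 0;
  for (int i = lo; i < hi; ++i) npos += y[idx[i]];
  T.prob[node] = (double)npos / n;
  if (npos == 0 || npos == n || n < 2) return; // pure or too small: leaf

  const int p = X.ncol();
  // partial Fisher-Yates: first mtry entries of featpool are the candidates
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)std::floor(R::unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(featpool[i], featpool[j]);
  }

  double best_score = -1.0;
  int best_f = -1;
  double best_thr = 0.0;
  const double parent = (double)npos * (n - npos) / n; // n * gini/2 form

  for (int m = 0; m < mtry; ++m) {
    int f = featpool[m];
    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
    std::sort(buf.begin(), buf.end());
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += buf[i].second;
      if (buf[i + 1].first <= buf[i].first) continue; // not a valid cut
      int nl = i + 1, nr = n - nl;
      int rpos = npos - lpos;
      // impurity decrease (up to constant factor)
      double score = parent - (double)lpos * (nl - lpos) / nl -
                     (double)rpos * (nr - rpos) / nr;
      if (score > best_score + 1e-12) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }
  if (best_f < 0 || best_score <= 1e-12) return; // no useful split: leaf

  // partition idx[lo:hi) by x <= thr
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return; // degenerate, keep leaf

  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  int lnode = T.add();
  int rnode = T.add();
  T.left[node] = lnode;
  T.right[node] = rnode;
  build_node(X, y, idx, lo, mid, lnode, T, mtry, featpool, buf);
  build_node(X, y, idx, mid, hi, rnode, T, mtry, featpool, buf);
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List forest(n_trees);
  std::vector<int> featpool(p);
  std::vector<std::pair<double,int>> buf;
  buf.reserve(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < p; ++i) featpool[i] = i;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(R::unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j; // bootstrap with replacement
    }
    TreeNodes T;
    T.add();
    build_node(X, y, idx, 0, n, 0, T, mtry, featpool, buf);
    int nn = (int)T.feat.size();
    NumericMatrix tm(nn, 5);
    for (int i = 0; i < nn; ++i) {
      tm(i, 0) = T.feat[i]; tm(i, 1) = T.thr[i];
      tm(i, 2) = T.left[i]; tm(i, 3) = T.right[i];
      tm(i, 4) = T.prob[i];
    }
    forest[t] = tm;
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int nt = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tm = forest[t];
    const int nn = tm.nrow();
    if (tm.ncol() != 5) stop("malformed tree table");
    for (int i = 0; i < n; ++i) {
      int node = 0, steps = 0;
      while (tm(node, 0) >= 0) {
        if (++steps > nn) stop("malformed tree: cyclic node references");
        int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) : (int)tm(node, 3);
        if (node < 0 || node >= nn) stop("malformed tree: node index out of range");
      }
      out[i] += tm(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
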