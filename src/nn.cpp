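#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

// Exact 3D nearest-neighbor search on a static reference cloud.
// A median-split kd-tree is built once per reference cloud and queried for
// every moving point; queries prune subtrees farther than the current best.
// Exactness (no approximation) is part of the registration contract and is
// checked against a brute-force oracle in the test suite.

namespace {

struct KdTree {
  // points stored row-major: pts[3*i + d]
  std::vector<double> pts;
  // nodes laid out implicitly by recursion over idx[lo, hi)
  std::vector<int> idx;
  // per recursion-span split dimension, stored at the midpoint position
  std::vector<int> split_dim;
  int n;

  void build(const Rcpp::NumericMatrix &m) {
    n = m.nrow();
    pts.resize(3 * n);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) pts[3 * i + d] = m(i, d);
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    split_dim.assign(n, 0);
    build_rec(0, n);
  }

  void build_rec(int lo, int hi) {
    if (hi - lo <= 1) return;
    // split along the dimension with the largest spread
    double mn[3], mx[3];
    for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
    for (int i = lo; i < hi; ++i) {
      const double *p = &pts[3 * idx[i]];
      for (int d = 0; d < 3; ++d) {
        if (p[d] < mn[d]) mn[d] = p[d];
        if (p[d] > mx[d]) mx[d] = p[d];
      }
    }
    int dim = 0;
    double best = mx[0] - mn[0];
    for (int d = 1; d < 3; ++d)
      if (mx[d] - mn[d] > best) { best = mx[d] - mn[d]; dim = d; }
    int mid = lo + (hi - lo) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return pts[3 * a + dim] < pts[3 * b + dim]; });
    split_dim[mid] = dim;
    build_rec(lo, mid);
    build_rec(mid + 1, hi);
  }

  void query_rec(int lo, int hi, const double *q, int &best_i, double &best_d2) const {
    if (hi <= lo) return;
    int mid = lo + (hi - lo) / 2;
    const double *p = &pts[3 * idx[mid]];
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) { double t = q[d] - p[d]; d2 += t * t; }
    if (d2 < best_d2) { best_d2 = d2; best_i = idx[mid]; }
    if (hi - lo == 1) return;
    int dim = split_dim[mid];
    double diff = q[dim] - p[dim];
    if (diff <= 0.0) {
      query_rec(lo, mid, q, best_i, best_d2);
      if (diff * diff < best_d2) query_rec(mid + 1, hi, q, best_i, best_d2);
    } else {
      query_rec(mid + 1, hi, q, best_i, best_d2);
      if (diff * diff < best_d2) query_rec(lo, mid, q, best_i, best_d2);
    }
  }

  void query(const double *q, int &best_i, double &best_d2) const {
    best_i = -1;
    best_d2 = R_PosInf;
    query_rec(0, n, q, best_i, best_d2);
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP cpp_kdtree_build(Rcpp::NumericMatrix ref) {
  if (ref.ncol() != 3) Rcpp::stop("reference must be an n x 3 matrix");
  if (ref.nrow() < 1) Rcpp::stop("reference cloud is empty");
  Rcpp::XPtr<KdTree> tree(new KdTree(), true);
  tree->build(ref);
  return tree;
}

// [[Rcpp::export]]
Rcpp::List cpp_kdtree_query(SEXP tree_ptr, Rcpp::NumericMatrix query) {
  Rcpp::XPtr<KdTree> tree(tree_ptr);
  if (query.ncol() != 3) Rcpp::stop("query must be an n x 3 matrix");
  int m = query.nrow();
  Rcpp::IntegerVector index(m);
  Rcpp::NumericVector dist(m);
  double q[3];
  for (int i = 0; i < m; ++i) {
    for (int d = 0; d < 3; ++d) q[d] = query(i, d);
    int bi;
    double bd2;
    tree->query(q, bi, bd2);
    index[i] = bi + 1;  // 1-based for R
    dist[i] = std::sqrt(bd2);
  }
  return Rcpp::List::create(Rcpp::Named("index") = index,
                            Rcpp::Named("dist") = dist);
}
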