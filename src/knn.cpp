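#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 2D kd-tree over contact coordinates (pos1, pos2).  Exact k-nearest-
// neighbour queries: results are identical to brute-force all-pairs
// distances (verified against an R oracle in the test suite).

struct KDTree {
  std::vector<double> x, y;     // point coordinates
  std::vector<int> idx;         // permutation: tree order -> original index
  std::vector<int> split_dim;   // node split dimension (implicit balanced tree)
  int n;

  void build(const NumericVector &xs, const NumericVector &ys) {
    n = xs.size();
    x.assign(xs.begin(), xs.end());
    y.assign(ys.begin(), ys.end());
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    build_rec(0, n, 0);
  }

  void build_rec(int lo, int hi, int dim) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    const std::vector<double> &c = dim == 0 ? x : y;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return c[a] < c[b]; });
    build_rec(lo, mid, 1 - dim);
    build_rec(mid + 1, hi, 1 - dim);
  }

  // k nearest squared distances to (qx,qy), excluding original index `skip`
  // (pass -1 for none).  Heap holds (dist2, original index).
  void query(double qx, double qy, int k, int skip,
             std::vector<double> &out) const {
    std::priority_queue<std::pair<double, int> > heap;
    query_rec(0, n, 0, qx, qy, k, skip, heap);
    out.resize(heap.size());
    for (int i = (int)heap.size() - 1; i >= 0; --i) {
      out[i] = heap.top().first;
      heap.pop();
    }
  }

  void query_rec(int lo, int hi, int dim, double qx, double qy, int k,
                 int skip, std::priority_queue<std::pair<double, int> > &heap) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = idx[mid];
    double dx = x[p] - qx, dy = y[p] - qy;
    double d2 = dx * dx + dy * dy;
    if (p != skip) {
      if ((int)heap.size() < k) heap.push(std::make_pair(d2, p));
      else if (d2 < heap.top().first) { heap.pop(); heap.push(std::make_pair(d2, p)); }
    }
    double diff = (dim == 0 ? qx - x[p] : qy - y[p]);
    int first_lo = diff < 0 ? lo : mid + 1;
    int first_hi = diff < 0 ? mid : hi;
    int second_lo = diff < 0 ? mid + 1 : lo;
    int second_hi = diff < 0 ? hi : mid;
    query_rec(first_lo, first_hi, 1 - dim, qx, qy, k, skip, heap);
    if ((int)heap.size() < k || diff * diff < heap.top().first)
      query_rec(second_lo, second_hi, 1 - dim, qx, qy, k, skip, heap);
  }
};

// Signed two-sample KS statistic between sorted samples a and b using the
// "<=" ECDF convention.  Returns (D, signed_D) where signed_D = F_a - F_b
// at the first (smallest-value) argmax of |F_a - F_b|; positive means a is
// stochastically smaller (denser at short distances).
static void ks_signed(const std::vector<double> &a, const std::vector<double> &b,
                      double &D, double &signedD) {
  long long n1 = (long long)a.size(), n2 = (long long)b.size();
  size_t i = 0, j = 0;
  // exact integer arithmetic: diff * n1 * n2; argmax ties keep the first
  // (smallest distance), matching the R reference implementation
  long long best = 0, best_signed = 0;
  while (i < a.size() || j < b.size()) {
    double v;
    if (i < a.size() && (j >= b.size() || a[i] <= b[j])) v = a[i];
    else v = b[j];
    while (i < a.size() && a[i] <= v) ++i;
    while (j < b.size() && b[j] <= v) ++j;
    long long di = (long long)i * n2 - (long long)j * n1;
    long long adi = di < 0 ? -di : di;
    if (adi > best) { best = adi; best_signed = di; }
  }
  D = (double)best / (double)(n1 * n2);
  signedD = (double)best_signed / (double)(n1 * n2);
}

// Score query contacts against observed and expected contact clouds.
// obs_*: observed cis contacts of one chromosome; exp_*: expected cloud;
// query: 0-based indices into the observed arrays.  For each query the k
// nearest observed neighbours (self excluded) and k_exp nearest expected
// neighbours are collected and their distance distributions compared with
// the signed KS statistic.  Returns a matrix [D, signed_D] per query.
// [[Rcpp::export]]
NumericMatrix knn_score_cpp(NumericVector obs_x, NumericVector obs_y,
                            NumericVector exp_x, NumericVector exp_y,
                            IntegerVector query, int k, int k_exp) {
  KDTree tobs, texp;
  tobs.build(obs_x, obs_y);
  texp.build(exp_x, exp_y);
  int nq = query.size();
  NumericMatrix out(nq, 2);
  std::vector<double> d_obs, d_exp;
  for (int q = 0; q < nq; ++q) {
    int qi = query[q];
    double qx = obs_x[qi], qy = obs_y[qi];
    tobs.query(qx, qy, k, qi, d_obs);
    texp.query(qx, qy, k_exp, -1, d_exp);
    for (size_t t = 0; t < d_obs.size(); ++t) d_obs[t] = std::sqrt(d_obs[t]);
    for (size_t t = 0; t < d_exp.size(); ++t) d_exp[t] = std::sqrt(d_exp[t]);
    double D, sD;
    ks_signed(d_obs, d_exp, D, sD);
    out(q, 0) = D;
    out(q, 1) = sD;
  }
  return out;
}

// k nearest distances (not squared) from each query point to the cloud,
// excluding the query's own index when self_exclude is true (cloud == query
// set).  Exposed for the neighbour-contract tests.
// [[Rcpp::export]]
NumericMatrix knn_dist_cpp(NumericVector cloud_x, NumericVector cloud_y,
                           NumericVector qx, NumericVector qy,
                           IntegerVector self_idx, int k) {
  KDTree tree;
  tree.build(cloud_x, cloud_y);
  int nq = qx.size();
  NumericMatrix out(nq, k);
  std::vector<double> d;
  for (int i = 0; i < nq; ++i) {
    int skip = self_idx[i];
    tree.query(qx[i], qy[i], k, skip, d);
    for (int j = 0; j < k; ++j)
      out(i, j) = j < (int)d.size() ? std::sqrt(d[j]) : NA_REAL;
  }
  return out;
}
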