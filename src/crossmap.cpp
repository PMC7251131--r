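#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Squared Euclidean distance from row i to every row of mv, written into
// `dist2`. Column-major layout: one contiguous pass per embedding column.
// Rows within `exclusion` of i (and i itself) are set to +Inf.
static void row_dist2(const double* m, int n, int E, int i, int exclusion,
                      std::vector<double>& dist2) {
  std::fill(dist2.begin(), dist2.end(), 0.0);
  for (int c = 0; c < E; ++c) {
    const double* col = m + (std::size_t)c * n;
    const double vi = col[i];
    for (int j = 0; j < n; ++j) {
      const double d = vi - col[j];
      dist2[j] += d * d;
    }
  }
  const double inf = std::numeric_limits<double>::infinity();
  const int lo = std::max(0, i - exclusion), hi = std::min(n - 1, i + exclusion);
  for (int j = lo; j <= hi; ++j) dist2[j] = inf;
}

// Indices of the k smallest entries of dist2 (ties toward the smaller index),
// written into ord[0..k-1].
static void select_k(const std::vector<double>& dist2, int k,
                     std::vector<int>& ord) {
  const int n = dist2.size();
  ord.resize(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                    [&dist2](int a, int b) {
                      return dist2[a] < dist2[b] ||
                             (dist2[a] == dist2[b] && a < b);
                    });
}

// Simplex weights: w_i proportional to exp(-d_i / d_min) with d_min the
// smallest nonzero distance; if any distance is exactly zero, weight mass is
// uniform over the zero-distance entries only.
static void simplex_w(const std::vector<double>& d, std::vector<double>& w) {
  const int k = d.size();
  w.resize(k);
  double dmin_nz = -1.0;
  bool any_zero = false;
  for (int j = 0; j < k; ++j) {
    if (d[j] == 0.0) any_zero = true;
    else if (dmin_nz < 0.0 || d[j] < dmin_nz) dmin_nz = d[j];
  }
  double s = 0.0;
  if (any_zero) {
    for (int j = 0; j < k; ++j) { w[j] = (d[j] == 0.0) ? 1.0 : 0.0; s += w[j]; }
  } else {
    for (int j = 0; j < k; ++j) { w[j] = std::exp(-d[j] / dmin_nz); s += w[j]; }
  }
  for (int j = 0; j < k; ++j) w[j] /= s;
}

static void check_eligible(int n, int k, int exclusion) {
  // worst case (interior point) loses 2*exclusion + 1 rows
  if (n - (2 * exclusion + 1) < k)
    stop("too few eligible neighbours: need %d, have at most %d eligible rows",
         k, std::max(n - (2 * exclusion + 1), 0));
}

// Cross-map estimate: for each row t of the library manifold `mv` (built from
// the driver-side series V), take the k nearest neighbours of row t, map their
// time indices onto the target series values `u` (aligned so u[t] corresponds
// to row t), and return the simplex-weighted average — the estimate u_hat[t].
// [[Rcpp::export]]
NumericVector cpp_cross_map_estimate(NumericMatrix mv, NumericVector u,
                                     int k, int exclusion) {
  const int n = mv.nrow(), E = mv.ncol();
  if (u.size() != n) stop("u and mv must be aligned (same number of rows)");
  check_eligible(n, k, exclusion);
  NumericVector est(n);
  const double* m = REAL(mv);
  std::vector<double> dist2(n), dk(k), w;
  std::vector<int> ord;
  for (int i = 0; i < n; ++i) {
    row_dist2(m, n, E, i, exclusion, dist2);
    select_k(dist2, k, ord);
    for (int j = 0; j < k; ++j) dk[j] = std::sqrt(dist2[ord[j]]);
    simplex_w(dk, w);
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += w[j] * u[ord[j]];
    est[i] = s;
  }
  return est;
}

// Nearest neighbour (k = 1) of every row; used by the FNN dimension search.
// [[Rcpp::export]]
List cpp_nn1_all(NumericMatrix mv, int exclusion) {
  const int n = mv.nrow(), E = mv.ncol();
  check_eligible(n, 1, exclusion);
  IntegerVector out_idx(n);
  NumericVector out_d(n);
  const double* m = REAL(mv);
  std::vector<double> dist2(n);
  std::vector<int> ord;
  for (int i = 0; i < n; ++i) {
    row_dist2(m, n, E, i, exclusion, dist2);
    select_k(dist2, 1, ord);
    out_idx[i] = ord[0] + 1;
    out_d[i] = std::sqrt(dist2[ord[0]]);
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_d);
}

// Neighbour query for a single row (1-based `t` on input/output).
// [[Rcpp::export]]
List cpp_neighbors(NumericMatrix mv, int t, int k, int exclusion) {
  const int n = mv.nrow(), E = mv.ncol();
  check_eligible(n, k, exclusion);
  const double* m = REAL(mv);
  std::vector<double> dist2(n);
  std::vector<int> ord;
  row_dist2(m, n, E, t - 1, exclusion, dist2);
  select_k(dist2, k, ord);
  IntegerVector out_idx(k);
  NumericVector out_d(k);
  for (int j = 0; j < k; ++j) {
    out_idx[j] = ord[j] + 1;
    out_d[j] = std::sqrt(dist2[ord[j]]);
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_d);
}
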