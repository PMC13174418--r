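#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact k-nearest neighbours by brute force (Euclidean), self excluded.
// Ties on distance are broken by the lower point index so that runs are
// reproducible regardless of input order of equal distances.
// Returns an n x k matrix of 1-based indices.
// [[Rcpp::export(name = ".knn_exact")]]
IntegerMatrix knn_exact(const arma::mat& coords, const int k) {
  const int n = coords.n_rows;
  const int d = coords.n_cols;
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int>> buf(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = coords(i, c) - coords(j, c);
        s += diff * diff;
      }
      buf[m++] = std::make_pair(s, j);
    }
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end());
    for (int c = 0; c < k; ++c) out(i, c) = buf[c].second + 1;
  }
  return out;
}

// k nearest rows of `target` for every row of `query` (cross-set kNN,
// used for mutual-nearest-neighbour anchors). 1-based indices.
// [[Rcpp::export(name = ".knn_cross")]]
IntegerMatrix knn_cross(const arma::mat& query, const arma::mat& target,
                        const int k) {
  const int nq = query.n_rows;
  const int nt = target.n_rows;
  const int d = query.n_cols;
  if (k > nt) stop("k must not exceed the number of target points");
  IntegerMatrix out(nq, k);
  std::vector<std::pair<double, int>> buf(nt);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nt; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = query(i, c) - target(j, c);
        s += diff * diff;
      }
      buf[j] = std::make_pair(s, j);
    }
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end());
    for (int c = 0; c < k; ++c) out(i, c) = buf[c].second + 1;
  }
  return out;
}
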