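#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Full-data multinomial NLL of the skip-gram model, Sum_ij N_ij * -log
// softmax_j(u_i . V). N is passed in CSR form over its nonzero rows.
static double full_nll(const arma::mat& U, const arma::mat& V,
                       const std::vector<int>& row_ptr,
                       const std::vector<int>& col_idx,
                       const std::vector<double>& val) {
  const int C = U.n_rows;
  const int M = V.n_cols;
  arma::rowvec s(M);
  double nll = 0.0;
  for (int i = 0; i < C; ++i) {
    if (row_ptr[i] == row_ptr[i + 1]) continue;
    s = U.row(i) * V;
    const double smax = s.max();
    double z = 0.0;
    for (int j = 0; j < M; ++j) z += std::exp(s[j] - smax);
    const double lse = smax + std::log(z);
    for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) {
      nll += val[p] * (lse - s[col_idx[p]]);
    }
  }
  return nll;
}

// Mini-batch SGD on the skip-gram objective. Events are the multiset of
// (target, context) pairs with multiplicity N_ij, reshuffled every epoch with
// R's RNG (deterministic under set.seed). Within a batch, events sharing a
// target clone share one softmax evaluation; parameters update at batch
// end. An epoch whose full-data NLL increases is rejected: parameters are
// restored, the learning rate halved and the epoch retried, so the
// recorded loss history is non-increasing by construction.
// [[Rcpp::export(name = ".skipgram_sgd")]]
List skipgram_sgd(const IntegerVector ev_i, const IntegerVector ev_j,
                  arma::mat U, arma::mat V,
                  const IntegerVector n_row_ptr, const IntegerVector n_col_idx,
                  const NumericVector n_val,
                  double lr, const int epochs, const int batch_size,
                  const double min_rel_improve, const int max_retry) {
  RNGScope scope;
  const int T = ev_i.size();
  const int z = U.n_cols;
  const int M = V.n_cols;

  std::vector<int> rp(n_row_ptr.begin(), n_row_ptr.end());
  std::vector<int> ci(n_col_idx.begin(), n_col_idx.end());
  std::vector<double> vv(n_val.begin(), n_val.end());

  std::vector<int> order(T);
  for (int t = 0; t < T; ++t) order[t] = t;
  std::vector<std::pair<int, int>> batch(batch_size);
  arma::mat gV(z, M);
  arma::vec g(M), u(z), gu(z);

  const double init_nll = full_nll(U, V, rp, ci, vv) / T;
  std::vector<double> loss;
  loss.push_back(init_nll);
  double prev = init_nll;
  const double accept_tol = 1e-9 * std::fabs(init_nll) + 1e-12;

  arma::mat U_prev = U, V_prev = V;
  int epochs_run = 0;
  bool plateau = false;

  for (int ep = 0; ep < epochs && !plateau; ++ep) {
    U_prev = U;
    V_prev = V;
    int attempts = 0;
    double nll = prev;
    while (true) {
      // Fisher-Yates with R's RNG
      for (int t = T - 1; t > 0; --t) {
        int r = static_cast<int>(unif_rand() * (t + 1));
        if (r > t) r = t;
        std::swap(order[t], order[r]);
      }
      for (int b0 = 0; b0 < T; b0 += batch_size) {
        const int b1 = std::min(b0 + batch_size, T);
        const int B = b1 - b0;
        for (int t = 0; t < B; ++t) {
          batch[t] = std::make_pair(ev_i[order[b0 + t]], ev_j[order[b0 + t]]);
        }
        std::sort(batch.begin(), batch.begin() + B);
        gV.zeros();
        const double step = lr;  // per-event step, applied at batch end
        int t = 0;
        while (t < B) {
          const int i = batch[t].first;
          int t2 = t;
          while (t2 < B && batch[t2].first == i) ++t2;
          const int m = t2 - t;
          u = U.row(i).t();
          // softmax over contexts for target i
          g = V.t() * u;
          const double smax = g.max();
          double zsum = 0.0;
          for (int j = 0; j < M; ++j) {
            g[j] = std::exp(g[j] - smax);
            zsum += g[j];
          }
          g *= (static_cast<double>(m) / zsum);  // m * p
          for (int e = t; e < t2; ++e) g[batch[e].second] -= 1.0;
          gu = V * g;
          gV += u * g.t();
          U.row(i) -= (step * gu).t();
          t = t2;
        }
        V -= step * gV;
      }
      nll = full_nll(U, V, rp, ci, vv) / T;
      if (nll <= prev + accept_tol) break;
      U = U_prev;
      V = V_prev;
      lr *= 0.5;
      if (++attempts > max_retry) {
        nll = prev;
        plateau = true;
        break;
      }
    }
    if (nll > prev) nll = prev;  // guard against accept_tol slack
    loss.push_back(nll);
    ++epochs_run;
    if (!plateau && (prev - nll) < min_rel_improve * std::fabs(init_nll)) {
      plateau = true;
    }
    prev = nll;
  }

  return List::create(_["U"] = U, _["V"] = V,
                      _["loss"] = NumericVector(loss.begin(), loss.end()),
                      _["lr_final"] = lr, _["epochs_run"] = epochs_run);
}
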