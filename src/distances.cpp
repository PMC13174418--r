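#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pairwise Euclidean distances between rows of A and rows of B.
static arma::mat cross_dist(const arma::mat& A, const arma::mat& B) {
  arma::mat D(A.n_rows, B.n_rows);
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      D(i, j) = std::sqrt(arma::accu(arma::square(A.row(i) - B.row(j))));
    }
  }
  return D;
}

// V-statistic energy distance: 2 E|a-b| - E|a-a'| - E|b-b'| with all
// ordered pairs (diagonal included), which is exactly zero for identical
// samples.
static double energy_stat(const arma::mat& A, const arma::mat& B) {
  const arma::mat Dab = cross_dist(A, B);
  const arma::mat Daa = cross_dist(A, A);
  const arma::mat Dbb = cross_dist(B, B);
  return 2.0 * arma::mean(arma::vectorise(Dab)) -
         arma::mean(arma::vectorise(Daa)) - arma::mean(arma::vectorise(Dbb));
}

// Biased (V-statistic) squared MMD with an RBF kernel; bandwidth = median
// pairwise distance over the pooled sample unless supplied (> 0).
static double mmd_stat(const arma::mat& A, const arma::mat& B,
                       double bandwidth) {
  const arma::mat P = arma::join_cols(A, B);
  if (bandwidth <= 0.0) {
    const arma::uword n = P.n_rows;
    std::vector<double> d;
    d.reserve(n * (n - 1) / 2);
    for (arma::uword i = 0; i < n; ++i) {
      for (arma::uword j = i + 1; j < n; ++j) {
        d.push_back(std::sqrt(arma::accu(arma::square(P.row(i) - P.row(j)))));
      }
    }
    if (d.empty()) return 0.0;
    std::nth_element(d.begin(), d.begin() + d.size() / 2, d.end());
    bandwidth = d[d.size() / 2];
    if (bandwidth <= 0.0) bandwidth = 1.0;
  }
  const double s2 = 2.0 * bandwidth * bandwidth;
  auto kmean = [&](const arma::mat& X, const arma::mat& Y) {
    double s = 0.0;
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      for (arma::uword j = 0; j < Y.n_rows; ++j) {
        s += std::exp(-arma::accu(arma::square(X.row(i) - Y.row(j))) / s2);
      }
    }
    return s / (X.n_rows * Y.n_rows);
  };
  return kmean(A, A) + kmean(B, B) - 2.0 * kmean(A, B);
}

// Log-domain Sinkhorn with uniform marginals and squared-Euclidean cost,
// using epsilon scaling (anneal from a large regularisation down to the
// target, warm-starting the potentials) for fast convergence at small
// eps. Convergence is measured as the maximum log marginal-ratio
// |delta g| / eps. Returns the entropic OT cost <f,a> + <g,b>; NA on
// failure.
static double sinkhorn_cost(const arma::mat& C, const double eps,
                            const double tol, const int max_iter,
                            int* iters_used) {
  const int n = C.n_rows, m = C.n_cols;
  const double la = -std::log(static_cast<double>(n));
  const double lb = -std::log(static_cast<double>(m));
  arma::vec f(n, arma::fill::zeros), g(m, arma::fill::zeros);

  std::vector<double> stages;
  double e = std::max(eps, C.max() / 2.0);
  while (e > eps * 1.5) {
    stages.push_back(e);
    e /= 2.0;
  }
  stages.push_back(eps);

  int total_it = 0;
  bool ok = true;
  double W_prev = arma::datum::inf;
  for (size_t s_idx = 0; s_idx < stages.size(); ++s_idx) {
    const double e_cur = stages[s_idx];
    const bool last = (s_idx + 1 == stages.size());
    // a handful of warm-up sweeps per stage; on the last stage run until
    // the entropic cost stabilises
    const int stage_iter = last ? max_iter : 10;
    bool conv = false;
    for (int it = 0; it < stage_iter; ++it) {
      ++total_it;
      for (int i = 0; i < n; ++i) {
        double best = -arma::datum::inf;
        for (int j = 0; j < m; ++j) {
          best = std::max(best, (g[j] - C(i, j)) / e_cur + lb);
        }
        double s = 0.0;
        for (int j = 0; j < m; ++j) {
          s += std::exp((g[j] - C(i, j)) / e_cur + lb - best);
        }
        f[i] = -e_cur * (best + std::log(s));
      }
      double viol = 0.0;
      for (int j = 0; j < m; ++j) {
        double best = -arma::datum::inf;
        for (int i = 0; i < n; ++i) {
          best = std::max(best, (f[i] - C(i, j)) / e_cur + la);
        }
        double s = 0.0;
        for (int i = 0; i < n; ++i) {
          s += std::exp((f[i] - C(i, j)) / e_cur + la - best);
        }
        const double gnew = -e_cur * (best + std::log(s));
        viol = std::max(viol, std::fabs(gnew - g[j]));
        g[j] = gnew;
      }
      if (last) {
        const double W = arma::mean(f) + arma::mean(g);
        if (std::fabs(W - W_prev) < tol * (1.0 + std::fabs(W))) {
          conv = true;
          break;
        }
        W_prev = W;
      } else if (viol < tol * e_cur) {
        conv = true;
        break;
      }
    }
    if (last && !conv) ok = false;
  }
  if (iters_used != nullptr) *iters_used = total_it;
  if (!ok) return NA_REAL;
  return arma::mean(f) + arma::mean(g);
}

// Symmetric (self-transport) entropic cost W_eps(a, a) via the averaged
// fixed-point update f <- (f + T(f)) / 2, which converges where the plain
// alternating iteration oscillates.
static double sinkhorn_self_cost(const arma::mat& C, const double eps,
                                 const double tol, const int max_iter) {
  const int n = C.n_rows;
  const double la = -std::log(static_cast<double>(n));
  arma::vec f(n, arma::fill::zeros), fn(n);

  std::vector<double> stages;
  double e = std::max(eps, C.max() / 2.0);
  while (e > eps * 1.5) {
    stages.push_back(e);
    e /= 2.0;
  }
  stages.push_back(eps);

  bool ok = true;
  double W_prev = arma::datum::inf;
  for (size_t s_idx = 0; s_idx < stages.size(); ++s_idx) {
    const double e_cur = stages[s_idx];
    const bool last = (s_idx + 1 == stages.size());
    const int stage_iter = last ? max_iter : 10;
    bool conv = false;
    for (int it = 0; it < stage_iter; ++it) {
      for (int i = 0; i < n; ++i) {
        double best = -arma::datum::inf;
        for (int j = 0; j < n; ++j) {
          best = std::max(best, (f[j] - C(i, j)) / e_cur + la);
        }
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
          s += std::exp((f[j] - C(i, j)) / e_cur + la - best);
        }
        fn[i] = 0.5 * (f[i] - e_cur * (best + std::log(s)));
      }
      const double viol = arma::abs(fn - f).max();
      f = fn;
      if (last) {
        const double W = 2.0 * arma::mean(f);
        if (std::fabs(W - W_prev) < tol * (1.0 + std::fabs(W))) {
          conv = true;
          break;
        }
        W_prev = W;
      } else if (viol < tol * e_cur) {
        conv = true;
        break;
      }
    }
    if (last && !conv) ok = false;
  }
  if (!ok) return NA_REAL;
  return 2.0 * arma::mean(f);
}

static double sinkhorn_stat(const arma::mat& A, const arma::mat& B,
                            double eps, const double tol, const int max_iter) {
  auto sqcost = [](const arma::mat& X, const arma::mat& Y) {
    arma::mat C(X.n_rows, Y.n_rows);
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      for (arma::uword j = 0; j < Y.n_rows; ++j) {
        C(i, j) = arma::accu(arma::square(X.row(i) - Y.row(j)));
      }
    }
    return C;
  };
  const arma::mat Cab = sqcost(A, B);
  if (eps <= 0.0) {
    const arma::mat P = arma::join_cols(A, B);
    const arma::mat Cpp = sqcost(P, P);
    eps = 0.05 * arma::mean(arma::vectorise(Cpp));
    if (eps <= 0.0) return 0.0;  // all points identical
  }
  int it = 0;
  const bool same = (A.n_rows == B.n_rows) &&
    arma::approx_equal(A, B, "absdiff", 1e-300);
  const double wab = same ? sinkhorn_self_cost(Cab, eps, tol, max_iter)
                          : sinkhorn_cost(Cab, eps, tol, max_iter, &it);
  const double waa = sinkhorn_self_cost(sqcost(A, A), eps, tol, max_iter);
  const double wbb = sinkhorn_self_cost(sqcost(B, B), eps, tol, max_iter);
  if (!std::isfinite(wab) || !std::isfinite(waa) || !std::isfinite(wbb)) {
    stop("Sinkhorn scaling iterations did not converge within %d iterations",
         max_iter);
  }
  return std::max(0.0, wab - 0.5 * waa - 0.5 * wbb);
}

// [[Rcpp::export(name = ".energy_pair")]]
double energy_pair(const arma::mat& A, const arma::mat& B) {
  return energy_stat(A, B);
}

// [[Rcpp::export(name = ".mmd_pair")]]
double mmd_pair(const arma::mat& A, const arma::mat& B, double bandwidth) {
  return mmd_stat(A, B, bandwidth);
}

// [[Rcpp::export(name = ".sinkhorn_pair")]]
double sinkhorn_pair(const arma::mat& A, const arma::mat& B, double eps,
                     double tol, int max_iter) {
  return sinkhorn_stat(A, B, eps, tol, max_iter);
}

// Full C x C clone-to-clone distance matrix over per-clone cell sets.
// `index` holds 0-based row offsets into `coords` per clone, flattened,
// with `ptr` delimiting clones (CSR layout). method: 1 energy, 2 mmd,
// 3 sinkhorn.
// [[Rcpp::export(name = ".pairwise_clone_distance")]]
NumericMatrix pairwise_clone_distance(const arma::mat& coords,
                                      const IntegerVector ptr,
                                      const IntegerVector index,
                                      const int method,
                                      const double bandwidth,
                                      const double eps,
                                      const double tol,
                                      const int max_iter) {
  const int C = ptr.size() - 1;
  std::vector<arma::mat> sets(C);
  for (int c = 0; c < C; ++c) {
    const int n = ptr[c + 1] - ptr[c];
    arma::mat S(n, coords.n_cols);
    for (int t = 0; t < n; ++t) S.row(t) = coords.row(index[ptr[c] + t]);
    sets[c] = S;
  }
  NumericMatrix D(C, C);
  for (int i = 0; i < C; ++i) {
    for (int j = i + 1; j < C; ++j) {
      double d;
      switch (method) {
        case 1: d = energy_stat(sets[i], sets[j]); break;
        case 2: d = mmd_stat(sets[i], sets[j], bandwidth); break;
        default: d = sinkhorn_stat(sets[i], sets[j], eps, tol, max_iter);
      }
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
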