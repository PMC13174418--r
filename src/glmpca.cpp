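#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Poisson deviance of counts N against means MU.
static double deviance(const arma::mat& N, const arma::mat& MU) {
  double d = 0.0;
  for (arma::uword t = 0; t < N.n_elem; ++t) {
    const double n = N[t], mu = MU[t];
    d += (n > 0.0) ? 2.0 * (n * std::log(n / mu) - n + mu) : 2.0 * mu;
  }
  return d;
}

// Poisson log-linear factorisation log mu_ij = a_i + b_j + u_i . v_j,
// fitted by alternating damped Newton updates of each row (a_i, u_i) and
// each column (b_j, v_j). Given the other side fixed, rows (columns) are
// independent Poisson regressions, so per-row backtracking on the row
// objective makes the total deviance non-increasing across sweeps.
// [[Rcpp::export(name = ".glmpca_fit")]]
List glmpca_fit(const arma::mat& N, arma::mat U, arma::mat V,
                arma::vec a, arma::vec b,
                const int max_iter, const double tol) {
  const int C = N.n_rows, M = N.n_cols, z = U.n_cols;
  arma::mat MU(C, M);
  auto recompute_mu = [&]() {
    arma::mat ETA = U * V.t();
    ETA.each_col() += a;
    ETA.each_row() += b.t();
    MU = arma::exp(ETA);
  };
  recompute_mu();
  std::vector<double> dev_hist;
  dev_hist.push_back(deviance(N, MU));

  arma::mat Xr(M, z + 1), Xc(C, z + 1);
  arma::vec g(z + 1), delta(z + 1), eta_new, mu_new, theta(z + 1);
  bool converged = false;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    // --- row sweep: update (a_i, u_i) with V, b fixed ---
    Xr.col(0).ones();
    Xr.cols(1, z) = V;
    for (int i = 0; i < C; ++i) {
      arma::rowvec ni = N.row(i);
      arma::rowvec mui = MU.row(i);
      g = Xr.t() * (ni - mui).t();
      arma::mat H = Xr.t() * (Xr.each_col() % mui.t());
      H.diag() += 1e-10;
      if (!arma::solve(delta, H, g, arma::solve_opts::no_approx)) continue;
      // current Poisson negative log-likelihood (up to const) of row i
      arma::rowvec eta_i = a[i] + b.t() + (U.row(i) * V.t());
      double f_old = arma::accu(mui) - arma::dot(ni, eta_i);
      double t = 1.0;
      theta[0] = a[i];
      theta.subvec(1, z) = U.row(i).t();
      while (t > 1e-4) {
        arma::vec cand = theta + t * delta;
        arma::rowvec eta_c = cand[0] + b.t() +
          (cand.subvec(1, z).t() * V.t());
        arma::rowvec mu_c = arma::exp(eta_c);
        double f_new = arma::accu(mu_c) - arma::dot(ni, eta_c);
        if (std::isfinite(f_new) && f_new <= f_old) {
          a[i] = cand[0];
          U.row(i) = cand.subvec(1, z).t();
          MU.row(i) = mu_c;
          break;
        }
        t *= 0.5;
      }
    }
    // --- column sweep: update (b_j, v_j) with U, a fixed ---
    Xc.col(0).ones();
    Xc.cols(1, z) = U;
    for (int j = 0; j < M; ++j) {
      arma::vec nj = N.col(j);
      arma::vec muj = MU.col(j);
      g = Xc.t() * (nj - muj);
      arma::mat H = Xc.t() * (Xc.each_col() % muj);
      H.diag() += 1e-10;
      if (!arma::solve(delta, H, g, arma::solve_opts::no_approx)) continue;
      arma::vec eta_j = a + b[j] + U * V.row(j).t();
      double f_old = arma::accu(muj) - arma::dot(nj, eta_j);
      double t = 1.0;
      theta[0] = b[j];
      theta.subvec(1, z) = V.row(j).t();
      while (t > 1e-4) {
        arma::vec cand = theta + t * delta;
        arma::vec eta_c = a + cand[0] + U * cand.subvec(1, z);
        arma::vec mu_c = arma::exp(eta_c);
        double f_new = arma::accu(mu_c) - arma::dot(nj, eta_c);
        if (std::isfinite(f_new) && f_new <= f_old) {
          b[j] = cand[0];
          V.row(j) = cand.subvec(1, z).t();
          MU.col(j) = mu_c;
          break;
        }
        t *= 0.5;
      }
    }
    const double d_new = deviance(N, MU);
    const double d_old = dev_hist.back();
    dev_hist.push_back(std::min(d_new, d_old));
    if (d_old - d_new < tol * (std::fabs(dev_hist.front()) + 1e-12)) {
      converged = true;
      ++it;
      break;
    }
  }

  return List::create(_["U"] = U, _["V"] = V, _["alpha"] = a, _["beta"] = b,
                      _["deviance"] = NumericVector(dev_hist.begin(),
                                                    dev_hist.end()),
                      _["iterations"] = it, _["converged"] = converged);
}
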