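#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Fixed-step RK4 integration of the bilinear neural state equation
//   dz/dt = (A + sum_j u_j B_j) z + C u
// with inputs held constant within each step. bidx maps each B matrix to
// its input column (0-based).
// [[Rcpp::export]]
arma::mat dcm_rk4_cpp(const arma::mat& A, const Rcpp::List& B,
                      const arma::mat& C, const arma::mat& U,
                      const arma::uvec& bidx, double dt, arma::vec z) {
  const int n = U.n_rows;
  const int k = A.n_rows;
  arma::mat out(n, k);
  std::vector<arma::mat> Bm;
  for (int j = 0; j < B.size(); ++j) Bm.push_back(Rcpp::as<arma::mat>(B[j]));

  for (int t = 0; t < n; ++t) {
    arma::rowvec ut = U.row(t);
    arma::mat J = A;
    for (size_t j = 0; j < Bm.size(); ++j) {
      double uj = ut(bidx(j));
      if (uj != 0.0) J += uj * Bm[j];
    }
    arma::vec cu = C * ut.t();
    arma::vec k1 = J * z + cu;
    arma::vec k2 = J * (z + 0.5 * dt * k1) + cu;
    arma::vec k3 = J * (z + 0.5 * dt * k2) + cu;
    arma::vec k4 = J * (z + dt * k3) + cu;
    z += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (arma::norm(z) > 1e6) Rcpp::stop("integration diverged");
    out.row(t) = z.t();
  }
  return out;
}
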