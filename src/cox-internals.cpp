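// Compiled kernels for the penalized Cox fitter: the cyclic coordinate
// descent step on the local quadratic model (L1 families) and the observed
// information accumulation over risk sets (Newton families).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Maximize g'(b-b0) - 1/2 (b-b0)' H (b-b0) - t1 * |b|_1 by cyclic
// coordinate descent with soft-thresholding.
// [[Rcpp::export(name = ".cdQuadraticL1Cpp")]]
arma::vec cdQuadraticL1Cpp(const arma::vec& b0, const arma::vec& g,
                           const arma::mat& H, double t1,
                           int maxCycles, double tol) {
  const int P = b0.n_elem;
  arma::vec b = b0;
  arma::vec hd = H.diag();
  arma::vec Hd(P, arma::fill::zeros);  // H * (b - b0), kept incrementally
  for (int cyc = 0; cyc < maxCycles; ++cyc) {
    double delta = 0.0;
    for (int j = 0; j < P; ++j) {
      double cj = g[j] + hd[j] * b0[j] - Hd[j] + hd[j] * (b[j] - b0[j]);
      double nb = 0.0;
      if (cj > t1) nb = (cj - t1) / hd[j];
      else if (cj < -t1) nb = (cj + t1) / hd[j];
      double dj = nb - b[j];
      if (dj != 0.0) {
        Hd += H.col(j) * dj;
        b[j] = nb;
        double adj = std::fabs(dj);
        if (adj > delta) delta = adj;
      }
    }
    if (delta < tol) break;
  }
  return b;
}

// Observed information of the Breslow partial likelihood on time-sorted
// data: sum_k d_k [ S2_k / S0_k - xbar_k xbar_k' ] with S2_k the reverse
// cumulative sum of w_j x_j x_j' over the k-th risk set. f (1-based) holds
// the first sorted index of each risk set, in ascending time order.
// [[Rcpp::export(name = ".coxInfoCpp")]]
arma::mat coxInfoCpp(const arma::mat& X, const arma::vec& w,
                     const arma::ivec& f, const arma::vec& S0,
                     const arma::mat& xbar, const arma::ivec& d) {
  const int n = X.n_rows;
  const int K = f.n_elem;
  arma::mat info(X.n_cols, X.n_cols, arma::fill::zeros);
  arma::mat S2(X.n_cols, X.n_cols, arma::fill::zeros);
  int upper = n - 1;
  for (int k = K - 1; k >= 0; --k) {
    for (int j = upper; j >= f[k] - 1; --j)
      S2 += w[j] * (X.row(j).t() * X.row(j));
    info += d[k] * (S2 / S0[k] - xbar.row(k).t() * xbar.row(k));
    upper = f[k] - 2;
  }
  return 0.5 * (info + info.t());
}
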