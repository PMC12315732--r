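// Lawson-Hanson active-set non-negative least squares.
// Solves min ||A x - b||^2 s.t. x >= 0. Compiled because the Monte Carlo
// inversion performs ~1e5 solves per analysis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".nnls_cpp")]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    const double tol_rel = 1e-10, const int max_iter = -1) {
  const arma::uword n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec w = A.t() * (b - A * x);
  const double tol = tol_rel * arma::norm(A, "fro") * std::max(1.0, arma::norm(b, 2));
  int itmax = (max_iter > 0) ? max_iter : 3 * static_cast<int>(n) + 30;
  int outer = 0;

  auto solve_passive = [&](arma::vec& z) {
    arma::uvec idx(n);
    arma::uword np = 0;
    for (arma::uword j = 0; j < n; ++j) if (passive[j]) idx[np++] = j;
    idx.resize(np);
    z.zeros(n);
    if (np == 0) return idx;
    arma::mat Ap = A.cols(idx);
    arma::vec zp;
    bool ok = arma::solve(zp, Ap.t() * Ap, Ap.t() * b,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok || !zp.is_finite()) zp = arma::pinv(Ap) * b;
    for (arma::uword k = 0; k < np; ++k) z[idx[k]] = zp[k];
    return idx;
  };

  while (outer++ < itmax) {
    // most-violating zero-set coordinate
    int jmax = -1;
    double wmax = tol;
    for (arma::uword j = 0; j < n; ++j)
      if (!passive[j] && w[j] > wmax) { wmax = w[j]; jmax = static_cast<int>(j); }
    if (jmax < 0) break;
    passive[jmax] = true;

    arma::vec z;
    solve_passive(z);
    int inner = 0;
    while (inner++ < itmax) {
      bool feasible = true;
      double alpha = 1.0;
      for (arma::uword j = 0; j < n; ++j) {
        if (passive[j] && z[j] <= 0) {
          feasible = false;
          double a = x[j] / (x[j] - z[j]);
          if (a < alpha) alpha = a;
        }
      }
      if (feasible) break;
      x += alpha * (z - x);
      for (arma::uword j = 0; j < n; ++j)
        if (passive[j] && x[j] <= 1e-14) { passive[j] = false; x[j] = 0.0; }
      solve_passive(z);
    }
    x = z;
    w = A.t() * (b - A * x);
  }
  const double res = arma::norm(b - A * x, 2);
  return Rcpp::List::create(Rcpp::Named("x") = x, Rcpp::Named("residual") = res);
}
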