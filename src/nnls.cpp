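#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS for a single right-hand side.
// Solves min ||A x - b||_2 s.t. x >= 0.
static vec nnls_one(const mat& A, const vec& b, double tol) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);

  const uword itmax = 3 * n + 30;
  uword outer = 0;
  while (outer++ < itmax) {
    // most violating coefficient among the zero-constrained set
    double wmax = tol;
    sword t = -1;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (sword)j; }
    if (t < 0) break;
    passive[(uword)t] = true;

    // inner loop: least squares on the passive set, backtrack if infeasible
    for (uword inner = 0; inner < itmax; ++inner) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P = P.head(np);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast + solve_opts::no_approx);
      if (!ok) z = pinv(A.cols(P)) * b;

      if (z.min() > tol) {
        x.zeros();
        for (uword k = 0; k < np; ++k) x(P(k)) = z(k);
        break;
      }
      // step toward z until the first coefficient hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= tol) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword k = 0; k < np; ++k) {
        x(P(k)) += alpha * (z(k) - x(P(k)));
        if (x(P(k)) <= tol) { x(P(k)) = 0.0; passive[P(k)] = false; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

//' Non-negative least squares with multiple right-hand sides
//'
//' @param A numeric matrix (m x n), the design.
//' @param B numeric matrix (m x k); each column is solved independently.
//' @return list with \code{coef} (n x k) and \code{resid} (length-k residual
//'   2-norms).
//' @keywords internal
// [[Rcpp::export(name = ".nnls_multi")]]
Rcpp::List nnls_multi(const arma::mat& A, const arma::mat& B) {
  const uword k = B.n_cols;
  mat X(A.n_cols, k, fill::zeros);
  vec rnorm(k, fill::zeros);
  double tol = 10.0 * datum::eps * norm(A, 1) * (double)std::max(A.n_rows, A.n_cols);
  for (uword j = 0; j < k; ++j) {
    vec x = nnls_one(A, B.col(j), tol);
    X.col(j) = x;
    rnorm(j) = norm(B.col(j) - A * x, 2);
  }
  return Rcpp::List::create(Rcpp::Named("coef") = X,
                            Rcpp::Named("resid") = rnorm);
}
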