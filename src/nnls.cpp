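// Non-negative least squares on the normal equations (Lawson-Hanson active
// set, Bro & de Jong style), solving min ||Z x - b||^2 s.t. x >= 0 for many
// right-hand sides given ZtZ (F x F) and ZtB (F x n). F is small (the PARAFAC
// factor count), n is a tensor mode size, so the active-set loop runs in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec solve_passive(const mat& ZtZ, const vec& Ztb, const uvec& P) {
  mat A = ZtZ.submat(P, P);
  vec b = Ztb.elem(P);
  vec s;
  if (!solve(s, A, b, solve_opts::no_approx)) {
    s = pinv(A) * b;  // rank-deficient passive set
  }
  return s;
}

// [[Rcpp::export]]
arma::mat nnls_normal(const arma::mat& ZtZ, const arma::mat& ZtB) {
  const uword F = ZtZ.n_rows, n = ZtB.n_cols;
  mat X(F, n, fill::zeros);
  const double tol = 1e-12 * std::max(1.0, ZtZ.diag().max());

  for (uword col = 0; col < n; ++col) {
    vec Ztb = ZtB.col(col);
    vec x(F, fill::zeros);
    std::vector<bool> passive(F, false);
    vec w = Ztb;  // gradient at x = 0
    uword outer = 0, outer_max = 10 * F + 10;

    while (outer++ < outer_max) {
      // most violated KKT multiplier among the active (zero) set
      double wmax = -datum::inf;
      sword jmax = -1;
      for (uword j = 0; j < F; ++j) {
        if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
      }
      if (jmax < 0 || wmax <= tol) break;
      passive[(uword)jmax] = true;

      uword inner = 0, inner_max = 10 * F + 10;
      while (inner++ < inner_max) {
        std::vector<uword> pidx;
        for (uword j = 0; j < F; ++j) if (passive[j]) pidx.push_back(j);
        uvec P(pidx);
        vec s = solve_passive(ZtZ, Ztb, P);
        if (s.min() > 0) {
          x.zeros();
          x.elem(P) = s;
          break;
        }
        // step back to the feasible boundary, drop variables hitting zero
        double alpha = datum::inf;
        for (uword t = 0; t < P.n_elem; ++t) {
          if (s(t) <= 0) {
            double xi = x(P(t));
            double a = xi / (xi - s(t));
            if (a < alpha) alpha = a;
          }
        }
        if (!std::isfinite(alpha)) alpha = 0.0;
        for (uword t = 0; t < P.n_elem; ++t) {
          x(P(t)) += alpha * (s(t) - x(P(t)));
        }
        for (uword j = 0; j < F; ++j) {
          if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0.0; }
        }
        bool any_passive = false;
        for (uword j = 0; j < F; ++j) if (passive[j]) any_passive = true;
        if (!any_passive) break;
      }
      w = Ztb - ZtZ * x;
    }
    X.col(col) = x;
  }
  return X;
}
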