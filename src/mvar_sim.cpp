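#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Iterate the MVAR(p) recursion x_t = sum_r A_r x_{t-r} + e_t.
//
// A:           n x n x p array of lag coefficient matrices
// innovations: n x T matrix (already scaled by the innovation covariance);
//              drawn in R so that all randomness stays in R's RNG stream.
//
// Returns the full n x T trajectory (burn-in removal happens in R).
// [[Rcpp::export(name = ".mvar_recurse")]]
arma::mat mvar_recurse(const arma::cube& A, const arma::mat& innovations) {
  const arma::uword n = innovations.n_rows;
  const arma::uword T = innovations.n_cols;
  const arma::uword p = A.n_slices;
  arma::mat x = innovations;  // copy; x_t starts as e_t
  for (arma::uword t = 0; t < T; ++t) {
    const arma::uword rmax = (t < p) ? t : p;
    for (arma::uword r = 1; r <= rmax; ++r) {
      x.col(t) += A.slice(r - 1) * x.col(t - r);
    }
  }
  return x;
}
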