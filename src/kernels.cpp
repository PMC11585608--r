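#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Softmax over the second dimension of a (n, m, B) cube.
// [[Rcpp::export]]
arma::cube softmax2_cpp(const arma::cube& x) {
  arma::cube y(x.n_rows, x.n_cols, x.n_slices);
  for (arma::uword s = 0; s < x.n_slices; ++s) {
    const arma::mat& m = x.slice(s);
    arma::vec mx = arma::max(m, 1);
    arma::mat e = arma::exp(m.each_col() - mx);
    y.slice(s) = e.each_col() / arma::sum(e, 1);
  }
  return y;
}

// Backward of softmax2: dx = y * (g - rowsum(g * y)).
// [[Rcpp::export]]
arma::cube softmax2_bwd_cpp(const arma::cube& g, const arma::cube& y) {
  arma::cube dx(g.n_rows, g.n_cols, g.n_slices);
  for (arma::uword s = 0; s < g.n_slices; ++s) {
    arma::mat gy = g.slice(s) % y.slice(s);
    arma::vec rs = arma::sum(gy, 1);
    dx.slice(s) = gy - y.slice(s).each_col() % rs;
  }
  return dx;
}

// Layer norm over columns of an (n, C) matrix; returns y, xhat and the
// per-row inverse standard deviation needed by the backward pass.
// [[Rcpp::export]]
Rcpp::List layernorm_cpp(const arma::mat& x, const arma::vec& gamma,
                         const arma::vec& beta, const double eps) {
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec v = arma::mean(arma::square(xc), 1);
  arma::vec inv = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat = xc.each_col() % inv;
  arma::mat y = (xhat.each_row() % gamma.t()).each_row() + beta.t();
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List layernorm_bwd_cpp(const arma::mat& g, const arma::mat& xhat,
                             const arma::vec& inv, const arma::vec& gamma) {
  arma::vec dgamma = arma::sum(g % xhat, 0).t();
  arma::vec dbeta = arma::sum(g, 0).t();
  arma::mat dxh = g.each_row() % gamma.t();
  arma::vec m1 = arma::mean(dxh, 1);
  arma::vec m2 = arma::mean(dxh % xhat, 1);
  arma::mat dx = dxh.each_col() - m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
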