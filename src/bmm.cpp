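#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Batched matrix multiply over the third (slice) dimension of rank-3
// arrays.  Window attention reduces to thousands of tiny per-window
// matrix products; looping over them in R is dominated by interpreter
// overhead, so the loop lives here.
// [[Rcpp::export]]
arma::cube bmm_cpp(const arma::cube& A, const arma::cube& B,
                   const bool ta, const bool tb) {
  const arma::uword ns = A.n_slices;
  if (B.n_slices != ns) Rcpp::stop("bmm: slice counts differ");
  const arma::uword m = ta ? A.n_cols : A.n_rows;
  const arma::uword kA = ta ? A.n_rows : A.n_cols;
  const arma::uword kB = tb ? B.n_cols : B.n_rows;
  const arma::uword n = tb ? B.n_rows : B.n_cols;
  if (kA != kB) Rcpp::stop("bmm: inner dimensions differ");
  arma::cube C(m, n, ns);
  for (arma::uword s = 0; s < ns; ++s) {
    if (!ta && !tb)      C.slice(s) = A.slice(s) * B.slice(s);
    else if (!ta && tb)  C.slice(s) = A.slice(s) * B.slice(s).t();
    else if (ta && !tb)  C.slice(s) = A.slice(s).t() * B.slice(s);
    else                 C.slice(s) = A.slice(s).t() * B.slice(s).t();
  }
  return C;
}
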