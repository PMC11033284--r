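#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Batched matrix multiply over the third (slice) dimension.
// Supported transpose combinations: (false,false) and (false,true).
// [[Rcpp::export]]
arma::cube bmm_cpp(const arma::cube& A, const arma::cube& B,
                   bool ta, bool tb) {
  const uword nb = A.n_slices;
  if (B.n_slices != nb) Rcpp::stop("bmm: slice counts differ");
  const uword n = ta ? A.n_cols : A.n_rows;
  const uword m = tb ? B.n_rows : B.n_cols;
  cube out(n, m, nb);
  for (uword b = 0; b < nb; ++b) {
    if (!ta && !tb)      out.slice(b) = A.slice(b) * B.slice(b);
    else if (!ta && tb)  out.slice(b) = A.slice(b) * B.slice(b).t();
    else if (ta && !tb)  out.slice(b) = A.slice(b).t() * B.slice(b);
    else                 out.slice(b) = A.slice(b).t() * B.slice(b).t();
  }
  return out;
}

// Shared weight on the right: out.slice(b) = A.slice(b) * W (or * W.t()).
// [[Rcpp::export]]
arma::cube rmm_cpp(const arma::cube& A, const arma::mat& W, bool tw) {
  const uword nb = A.n_slices;
  const uword m = tw ? W.n_rows : W.n_cols;
  cube out(A.n_rows, m, nb);
  for (uword b = 0; b < nb; ++b) {
    if (tw) out.slice(b) = A.slice(b) * W.t();
    else    out.slice(b) = A.slice(b) * W;
  }
  return out;
}

// Weight gradient of rmm: sum_b A.slice(b).t() * G.slice(b).
// [[Rcpp::export]]
arma::mat rmm_grad_cpp(const arma::cube& A, const arma::cube& G) {
  mat out(A.n_cols, G.n_cols, fill::zeros);
  for (uword b = 0; b < A.n_slices; ++b)
    out += A.slice(b).t() * G.slice(b);
  return out;
}

// Shared matrix on the left: out.slice(b) = W * A.slice(b) (or W.t() *).
// [[Rcpp::export]]
arma::cube lmm_cpp(const arma::mat& W, const arma::cube& A, bool tw) {
  const uword nb = A.n_slices;
  const uword n = tw ? W.n_cols : W.n_rows;
  cube out(n, A.n_cols, nb);
  for (uword b = 0; b < nb; ++b) {
    if (tw) out.slice(b) = W.t() * A.slice(b);
    else    out.slice(b) = W * A.slice(b);
  }
  return out;
}

// Left-matrix gradient of lmm: sum_b G.slice(b) * A.slice(b).t().
// [[Rcpp::export]]
arma::mat lmm_grad_cpp(const arma::cube& G, const arma::cube& A) {
  mat out(G.n_rows, A.n_rows, fill::zeros);
  for (uword b = 0; b < A.n_slices; ++b)
    out += G.slice(b) * A.slice(b).t();
  return out;
}
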