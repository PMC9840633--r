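// Condensed pairwise Euclidean distances, computed block-wise through BLAS
// (d^2(i,j) = |x_i|^2 + |x_j|^2 - 2 x_i.x_j). Only the condensed vector plus
// an O(block x n) temporary is ever materialized.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".dist_condensed_cpp")]]
NumericVector dist_condensed_cpp(const arma::mat& x, int block = 256) {
  const arma::uword n = x.n_rows;
  if (n < 2) stop("need at least 2 rows");
  const double nd = static_cast<double>(n);
  const double len = nd * (nd - 1.0) / 2.0;
  if (len > 2147483647.0) stop("too many pairs for an R vector index");
  NumericVector out(static_cast<R_xlen_t>(len));
  arma::vec nrm = arma::sum(arma::square(x), 1);

  for (arma::uword i0 = 0; i0 < n; i0 += block) {
    arma::uword i1 = std::min<arma::uword>(i0 + block, n);
    // inner products of rows i0..i1-1 against all rows
    arma::mat g = x.rows(i0, i1 - 1) * x.t();
    for (arma::uword i = i0; i < i1; ++i) {
      // condensed offset of pair (i, i+1), 0-based row-major over i<j
      double base = nd * i - (static_cast<double>(i) * (i + 1.0)) / 2.0 - i - 1.0;
      const double ni = nrm(i);
      for (arma::uword j = i + 1; j < n; ++j) {
        double d2 = ni + nrm(j) - 2.0 * g(i - i0, j);
        if (d2 < 0) d2 = 0;
        out[static_cast<R_xlen_t>(base + j)] = std::sqrt(d2);
      }
    }
  }
  return out;
}
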