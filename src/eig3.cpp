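// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Batched symmetric 3x3 eigendecomposition. J is n x 6 with columns
// (Jxx, Jxy, Jxz, Jyy, Jyz, Jzz). Returns eigenvalues sorted DESCENDING
// (values: n x 3) and the matched orthonormal eigenvectors (vectors: n x 9,
// columns v1x v1y v1z v2x v2y v2z v3x v3y v3z).
// [[Rcpp::export]]
List cpp_eig3_field(NumericMatrix J) {
  const int n = J.nrow();
  NumericMatrix values(n, 3), vectors(n, 9);
  arma::mat33 A;
  arma::vec3 ev;
  arma::mat33 V;
  for (int r = 0; r < n; ++r) {
    A(0, 0) = J(r, 0); A(0, 1) = J(r, 1); A(0, 2) = J(r, 2);
    A(1, 0) = J(r, 1); A(1, 1) = J(r, 3); A(1, 2) = J(r, 4);
    A(2, 0) = J(r, 2); A(2, 1) = J(r, 4); A(2, 2) = J(r, 5);
    arma::eig_sym(ev, V, A);  // ascending
    for (int c = 0; c < 3; ++c) {
      const int src = 2 - c;  // flip to descending
      values(r, c) = ev(src);
      vectors(r, 3 * c + 0) = V(0, src);
      vectors(r, 3 * c + 1) = V(1, src);
      vectors(r, 3 * c + 2) = V(2, src);
    }
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}
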