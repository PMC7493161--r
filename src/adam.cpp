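#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update for one parameter tensor. The caller owns all
// four buffers exclusively (they are package-internal optimizer state), so
// mutating them in place is safe and avoids four large temporaries per
// layer per minibatch.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector w, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1,
                         double beta2, double eps, double c1, double c2) {
  R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  double *W = REAL(w), *M = REAL(m), *V = REAL(v), *G = REAL(g);
  // lr * (m/c1) / (sqrt(v/c2) + eps) == a * m / (sqrt(v) + e2)
  const double sc2 = std::sqrt(c2);
  const double a = lr * sc2 / c1;
  const double e2 = eps * sc2;
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = G[i];
    double mi = beta1 * M[i] + (1.0 - beta1) * gi;
    double vi = beta2 * V[i] + (1.0 - beta2) * gi * gi;
    M[i] = mi;
    V[i] = vi;
    W[i] -= a * mi / (std::sqrt(vi) + e2);
  }
}
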