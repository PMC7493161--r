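// Dense forward/backward passes for the fully connected nets. Inputs are
// aliased (no copy); outputs are freshly allocated R matrices so the R side
// keeps ordinary value semantics. Activation codes: 0 linear, 1 relu,
// 2 sigmoid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat aliasMat(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// [[Rcpp::export]]
List mlp_forward_cpp(List W, List b, IntegerVector act, NumericMatrix X,
                     bool cache) {
  int L = W.size();
  int n = X.nrow();
  List H(L);
  NumericMatrix prevR = X;
  for (int l = 0; l < L; ++l) {
    NumericMatrix WlR = W[l];
    NumericVector blR = b[l];
    arma::mat Wl = aliasMat(WlR);
    arma::rowvec bl(blR.begin(), blR.size(), false, true);
    NumericMatrix outR(n, (int) Wl.n_cols);
    {
      arma::mat prev = aliasMat(prevR);
      arma::mat out(outR.begin(), n, Wl.n_cols, false, true);
      out = prev * Wl;
      out.each_row() += bl;
      switch (act[l]) {
      case 1:
        out.transform([](double z) { return z > 0.0 ? z : 0.0; });
        break;
      case 2:
        out.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
        break;
      default:
        break;
      }
    }
    H[l] = outR;
    prevR = outR;
  }
  if (cache) return List::create(_["out"] = prevR, _["H"] = H);
  return List::create(_["out"] = prevR);
}

// [[Rcpp::export]]
List mlp_backward_cpp(List W, IntegerVector act, NumericMatrix X, List H,
                      NumericMatrix dOut) {
  int L = W.size();
  int n = X.nrow();
  List gW(L), gb(L);
  NumericMatrix dHR = dOut;
  NumericMatrix dXR;
  for (int l = L - 1; l >= 0; --l) {
    NumericMatrix WlR = W[l];
    NumericMatrix HlR = H[l];
    arma::mat Wl = aliasMat(WlR);
    arma::mat Hl = aliasMat(HlR);
    arma::mat dH = aliasMat(dHR);
    arma::mat dZ(dH.n_rows, dH.n_cols);
    {
      const double *ph = Hl.memptr(), *pd = dH.memptr();
      double *pz = dZ.memptr();
      const arma::uword ne = dZ.n_elem;
      switch (act[l]) {
      case 1:
        for (arma::uword i = 0; i < ne; ++i)
          pz[i] = ph[i] > 0.0 ? pd[i] : 0.0;
        break;
      case 2:
        for (arma::uword i = 0; i < ne; ++i)
          pz[i] = pd[i] * ph[i] * (1.0 - ph[i]);
        break;
      default:
        std::copy(pd, pd + ne, pz);
        break;
      }
    }
    NumericMatrix AlR = (l == 0) ? X : (NumericMatrix) H[l - 1];
    arma::mat Al = aliasMat(AlR);
    NumericMatrix gWl((int) Wl.n_rows, (int) Wl.n_cols);
    {
      arma::mat gWa(gWl.begin(), Wl.n_rows, Wl.n_cols, false, true);
      gWa = Al.t() * dZ;
    }
    NumericVector gbl((int) Wl.n_cols);
    {
      arma::rowvec gba(gbl.begin(), Wl.n_cols, false, true);
      gba = arma::sum(dZ, 0);
    }
    gW[l] = gWl;
    gb[l] = gbl;
    NumericMatrix outR(n, (int) Wl.n_rows);
    {
      arma::mat dHa(outR.begin(), n, Wl.n_rows, false, true);
      dHa = dZ * Wl.t();
    }
    dHR = outR;
    dXR = outR;
  }
  return List::create(_["gW"] = gW, _["gb"] = gb, _["dX"] = dXR);
}
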