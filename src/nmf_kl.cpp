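#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& V, const mat& WH) {
  // generalised Kullback-Leibler divergence D(V || WH)
  double d = 0.0;
  const double* v = V.memptr();
  const double* wh = WH.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (v[i] > 0.0)
      d += v[i] * std::log(v[i] / wh[i]) - v[i] + wh[i];
    else
      d += wh[i];
  }
  return d;
}

// Multiplicative-update NMF minimising KL divergence (Brunet variant).
// V: n x m (non-negative), W: n x k, H: k x m (positive initial values).
// Convergence: relative change of the objective, checked every `check` iters.
// [[Rcpp::export]]
Rcpp::List nmf_kl_update(const arma::mat& V, arma::mat W, arma::mat H,
                         int max_iter, double tol) {
  const double eps = 1e-16;
  const int check = 10;
  double prev = datum::inf, obj = datum::inf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    mat WH = W * H;
    WH.for_each([eps](mat::elem_type& x) { if (x < eps) x = eps; });
    // H update: H_{jm} <- H_{jm} * sum_i W_ij V_im / WH_im / sum_i W_ij
    mat Q = V / WH;
    colvec wsum = sum(W, 0).t();
    wsum.for_each([eps](colvec::elem_type& x) { if (x < eps) x = eps; });
    H %= (W.t() * Q);
    H.each_col() /= wsum;
    // W update with refreshed WH
    WH = W * H;
    WH.for_each([eps](mat::elem_type& x) { if (x < eps) x = eps; });
    Q = V / WH;
    rowvec hsum = sum(H, 1).t();
    hsum.for_each([eps](rowvec::elem_type& x) { if (x < eps) x = eps; });
    W %= (Q * H.t());
    W.each_row() /= hsum;
    if (it % check == 0 || it == max_iter) {
      mat WH2 = W * H;
      WH2.for_each([eps](mat::elem_type& x) { if (x < eps) x = eps; });
      obj = kl_div(V, WH2);
      if (std::isfinite(prev) &&
          std::fabs(prev - obj) <= tol * std::fabs(prev))
        break;
      prev = obj;
    }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
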