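// Batch cost/gradient kernel for the fully connected surrogate networks.
// Mirrors the reference R implementation (hidden ReLU layers, affine
// output, worst-percentile cost): one forward pass keeping activations,
// exact subgradient of the percentile cost, one backward pass. Kept in
// C++ because this is the training hot loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// mean of the largest `upper_fraction`% entries of |err| (or err^2), with
// ties at the cutoff included, plus d cost / d err as `w`
static double percentile_select(const mat& e, double upper_fraction,
                                umat& sel, double& K) {
  const uword n = e.n_elem;
  uword k = (uword)std::ceil(upper_fraction / 100.0 * (double)n);
  if (k < 1) k = 1;
  vec es = sort(vectorise(e), "descend");
  double cut = es(k - 1);
  sel = (e >= cut);
  K = (double)accu(sel);
  return accu(e % conv_to<mat>::from(sel)) / K;
}

// [[Rcpp::export(name = ".ann_cost_grad_cpp")]]
Rcpp::List ann_cost_grad_cpp(Rcpp::List W, Rcpp::List b,
                             const arma::mat& X, const arma::mat& Y,
                             double upper_fraction, bool squared) {
  const int L = W.size();
  std::vector<mat> Wm(L);
  std::vector<rowvec> bv(L);
  for (int l = 0; l < L; ++l) {
    Wm[l] = Rcpp::as<mat>(W[l]);
    bv[l] = Rcpp::as<rowvec>(b[l]);
  }

  // forward, keeping post-activation outputs and ReLU masks
  std::vector<mat> acts(L + 1);
  std::vector<umat> relu(L);
  acts[0] = X;
  for (int l = 0; l < L; ++l) {
    mat A = acts[l] * Wm[l];
    A.each_row() += bv[l];
    if (l < L - 1) {
      relu[l] = (A > 0);
      A = A % conv_to<mat>::from(relu[l]);
    }
    acts[l + 1] = A;
  }

  mat d = acts[L] - Y;
  mat e = squared ? mat(d % d) : mat(abs(d));
  umat sel;
  double K = 1.0;
  double cost = percentile_select(e, upper_fraction, sel, K);

  mat delta;
  if (squared)
    delta = 2.0 * (d % conv_to<mat>::from(sel)) / K;
  else
    delta = (sign(d) % conv_to<mat>::from(sel)) / K;

  // backward
  Rcpp::List gW(L), gb(L);
  for (int l = L - 1; l >= 0; --l) {
    gW[l] = Rcpp::wrap(mat(acts[l].t() * delta));
    gb[l] = Rcpp::wrap(rowvec(sum(delta, 0)));
    if (l > 0) {
      delta = delta * Wm[l].t();
      delta = delta % conv_to<mat>::from(relu[l - 1]);
    }
  }
  return Rcpp::List::create(Rcpp::Named("cost") = cost,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
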