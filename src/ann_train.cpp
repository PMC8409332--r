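// Fused training kernel: one call runs a whole epoch of mini-batch Adam
// on the worst-percentile cost, updating the flat parameter and moment
// vectors in place (they are allocated by and owned by train_ann). Layer
// weights live in one flat vector laid out [W1, b1, W2, b2, ...]
// (column-major W), viewed through zero-copy armadillo matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Views {
  std::vector<mat> W;
  std::vector<rowvec> b;
};

// zero-copy views into a flat parameter vector. reserve() is essential:
// vector growth would copy-construct earlier mats, which for aux-memory
// views silently allocates owning copies and detaches them.
static Views make_views(double* p, const ivec& sizes) {
  Views v;
  const int L = sizes.n_elem - 1;
  v.W.reserve(L);
  v.b.reserve(L);
  std::size_t off = 0;
  for (int l = 0; l < L; ++l) {
    v.W.emplace_back(p + off, sizes[l], sizes[l + 1], false, true);
    off += (std::size_t)sizes[l] * sizes[l + 1];
    v.b.emplace_back(p + off, sizes[l + 1], false, true);
    off += sizes[l + 1];
  }
  return v;
}

// [[Rcpp::export(name = ".ann_adam_epoch_cpp")]]
Rcpp::List ann_adam_epoch_cpp(Rcpp::NumericVector theta,
                              Rcpp::NumericVector mvec,
                              Rcpp::NumericVector vvec,
                              const arma::mat& X, const arma::mat& Y,
                              const arma::uvec& order, int batch_size,
                              int t_start, double lr,
                              double upper_fraction, bool squared,
                              double beta1, double beta2, double eps,
                              const arma::ivec& sizes) {
  const int L = sizes.n_elem - 1;
  Views Wv = make_views(theta.begin(), sizes);
  Views Mv = make_views(mvec.begin(), sizes);
  Views Vv = make_views(vvec.begin(), sizes);

  const uword n = order.n_elem;
  const int n_batches = std::max(1, (int)(n / (uword)batch_size));
  vec batch_costs(n_batches);
  int t = t_start;

  std::vector<mat> acts(L + 1), relu(L - 1 > 0 ? L - 1 : 0);
  for (int b = 0; b < n_batches; ++b) {
    uword lo = (uword)b * batch_size;
    uword hi = std::min(n, lo + (uword)batch_size) - 1;
    uvec idx = order.subvec(lo, hi);
    acts[0] = X.rows(idx);
    mat Yb = Y.rows(idx);

    for (int l = 0; l < L; ++l) {
      mat A = acts[l] * Wv.W[l];
      A.each_row() += Wv.b[l];
      if (l < L - 1) {
        A.transform([](double x) { return x > 0 ? x : 0.0; });
        relu[l] = A;          // post-activation; mask recovered as A > 0
      }
      acts[l + 1] = std::move(A);
    }

    mat d = acts[L] - Yb;
    mat e = squared ? mat(d % d) : mat(abs(d));
    uword k = (uword)std::ceil(upper_fraction / 100.0 * (double)e.n_elem);
    if (k < 1) k = 1;
    vec es = sort(vectorise(e), "descend");
    double cut = es(k - 1);
    umat sel = (e >= cut);
    double K = (double)accu(sel);
    batch_costs(b) = accu(e % conv_to<mat>::from(sel)) / K;
    if (!std::isfinite(batch_costs(b))) {
      return Rcpp::List::create(Rcpp::Named("costs") = batch_costs,
                                Rcpp::Named("t") = t,
                                Rcpp::Named("diverged") = true,
                                Rcpp::Named("at_batch") = b + 1);
    }

    mat delta = squared ? mat(2.0 * (d % conv_to<mat>::from(sel)) / K)
                        : mat((sign(d) % conv_to<mat>::from(sel)) / K);

    ++t;
    const double c1 = 1.0 - std::pow(beta1, t);
    const double c2 = 1.0 - std::pow(beta2, t);
    for (int l = L - 1; l >= 0; --l) {
      mat gW = acts[l].t() * delta;
      rowvec gb = sum(delta, 0);
      if (l > 0) {
        delta = delta * Wv.W[l].t();
        // ReLU mask: zero where the stored post-activation is zero
        delta.elem(find(relu[l - 1] <= 0)).zeros();
      }
      Mv.W[l] = beta1 * Mv.W[l] + (1.0 - beta1) * gW;
      Vv.W[l] = beta2 * Vv.W[l] + (1.0 - beta2) * (gW % gW);
      Wv.W[l] -= lr * (Mv.W[l] / c1) / (sqrt(Vv.W[l] / c2) + eps);
      Mv.b[l] = beta1 * Mv.b[l] + (1.0 - beta1) * gb;
      Vv.b[l] = beta2 * Vv.b[l] + (1.0 - beta2) * (gb % gb);
      Wv.b[l] -= lr * (Mv.b[l] / c1) / (sqrt(Vv.b[l] / c2) + eps);
    }
  }
  return Rcpp::List::create(Rcpp::Named("costs") = batch_costs,
                            Rcpp::Named("t") = t,
                            Rcpp::Named("diverged") = false,
                            Rcpp::Named("at_batch") = -1);
}
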