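// Full-batch training loop for the multilayer perceptron.
//
// Single precision throughout (the standard working precision for neural
// network training); the R side keeps a double-precision forward /
// input-gradient path for saliency and for finite-difference checks.
// No RNG here: initial parameters come from R, so all randomness is
// seeded at the R level.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

static fmat relu(const fmat& z) { return arma::clamp(z, 0.0f, arma::datum::inf); }

// Runtime-dispatched SIMD for the two elementwise hot loops: the build
// baseline ISA is conservative, so let GCC emit wider clones and pick
// the best one for the executing CPU.
#if defined(__GNUC__) && defined(__x86_64__)
#define HOT_LOOP __attribute__((target_clones("avx2", "sse4.2", "default")))
#else
#define HOT_LOOP
#endif

// Adam step, fused into one pass per parameter block. Uses the
// rescaled form W -= alpha_t * m / (sqrt(v) + eps_t) with
// alpha_t = lr * sqrt(1 - beta2^t) / (1 - beta1^t) and
// eps_t = eps * sqrt(1 - beta2^t), algebraically equal to the textbook
// bias-corrected update but one memory pass instead of several.
HOT_LOOP
static void adam_step(float* p, float* m, float* v, const float* g,
                      arma::uword n, float b1, float b2, float alpha_t,
                      float eps_t) {
  for (arma::uword i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0f - b1) * g[i];
    v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
    p[i] -= alpha_t * m[i] / (std::sqrt(v[i]) + eps_t);
  }
}

template <typename M>
static void adam_update(M& P, M& mom, M& vel, const M& G,
                        float b1, float b2, float alpha_t, float eps_t) {
  adam_step(P.memptr(), mom.memptr(), vel.memptr(), G.memptr(),
            P.n_elem, b1, b2, alpha_t, eps_t);
}

// In-place rectifier mask: zero entries of dZ where pre-activation <= 0.
HOT_LOOP
static void relu_mask_ptr(float* dz, const float* z, arma::uword n) {
  for (arma::uword i = 0; i < n; ++i) {
    if (z[i] <= 0.0f) dz[i] = 0.0f;
  }
}

static void relu_mask(fmat& dZ, const fmat& Zprev) {
  relu_mask_ptr(dZ.memptr(), Zprev.memptr(), dZ.n_elem);
}

// [[Rcpp::export]]
List cpp_train_mlp(List W_in, List b_in, const arma::mat& X_in,
                   const arma::ivec& y, int epochs, double lr,
                   double beta1, double beta2, double adam_eps) {
  const int L = W_in.size();
  const int n = X_in.n_rows;
  std::vector<fmat> W(L), mW(L), vW(L);
  std::vector<frowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = arma::conv_to<fmat>::from(as<arma::mat>(W_in[l]));
    b[l] = arma::conv_to<frowvec>::from(as<arma::rowvec>(b_in[l]));
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  const fmat X = arma::conv_to<fmat>::from(X_in);
  const float flr = (float)lr, fb1 = (float)beta1, fb2 = (float)beta2,
              feps = (float)adam_eps;
  arma::vec loss(epochs);

  std::vector<fmat> Z(L), A(L);  // pre- and post-activation per layer
  for (int e = 0; e < epochs; ++e) {
    // forward
    const fmat* inp = &X;
    for (int l = 0; l < L; ++l) {
      Z[l] = (*inp) * W[l];
      Z[l].each_row() += b[l];
      A[l] = (l < L - 1) ? relu(Z[l]) : Z[l];
      inp = &A[l];
    }
    // softmax + mean cross-entropy
    fmat P = arma::exp(Z[L - 1].each_col() - arma::max(Z[L - 1], 1));
    P.each_col() /= arma::sum(P, 1);
    double ce = 0.0;
    for (int i = 0; i < n; ++i)
      ce -= std::log(std::max((double)P(i, y[i]), 1e-30));
    loss[e] = ce / n;
    // backward (gradient of mean CE w.r.t. logits is (P - onehot)/n)
    fmat dZ = P;
    for (int i = 0; i < n; ++i) dZ(i, y[i]) -= 1.0f;
    dZ /= (float)n;
    // bias-corrected step size for this epoch
    const float t = (float)(e + 1);
    const float bc1 = 1.0f - std::pow(fb1, t);
    const float bc2 = 1.0f - std::pow(fb2, t);
    const float alpha_t = flr * std::sqrt(bc2) / bc1;
    const float eps_t = feps * std::sqrt(bc2);
    for (int l = L - 1; l >= 0; --l) {
      const fmat& layer_in = (l == 0) ? X : A[l - 1];
      const fmat dW = layer_in.t() * dZ;
      const frowvec db = arma::sum(dZ, 0);
      if (l > 0) {  // input gradient of layer 0 is not needed for updates
        dZ = dZ * W[l].t();
        relu_mask(dZ, Z[l - 1]);
      }
      adam_update(W[l], mW[l], vW[l], dW, fb1, fb2, alpha_t, eps_t);
      adam_update(b[l], mb[l], vb[l], db, fb1, fb2, alpha_t, eps_t);
    }
  }

  List W_out(L), b_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = arma::conv_to<arma::mat>::from(W[l]);
    b_out[l] = arma::conv_to<arma::rowvec>::from(b[l]);
  }
  return List::create(_["W"] = W_out, _["b"] = b_out, _["loss"] = loss);
}
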