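// Minibatch Adam training of the fully connected autoencoder, in single
// precision (the conventional arithmetic for neural-network training).
// All randomness (weight init, batch order) is drawn from R's RNG, so a
// set.seed() call in the R wrapper makes training bit-reproducible.
// Hot paths (bias+activation, Adam update) are fused single passes to keep
// per-epoch overhead low on small networks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::vector<arma::fmat> MatList;
typedef std::vector<arma::frowvec> VecList;

// Z <- act(Z + 1 b'), fused
static inline void bias_act(arma::fmat& Z, const arma::frowvec& b, int relu) {
  const arma::uword nr = Z.n_rows, nc = Z.n_cols;
  float* z = Z.memptr();
  const float* bb = b.memptr();
  for (arma::uword j = 0; j < nc; ++j) {
    const float bj = bb[j];
    float* col = z + j * nr;
    if (relu) {
      for (arma::uword i = 0; i < nr; ++i) {
        const float v = col[i] + bj;
        col[i] = v > 0.0f ? v : 0.0f;
      }
    } else {
      for (arma::uword i = 0; i < nr; ++i) col[i] += bj;
    }
  }
}

static inline void adam_step(float* p, float* m, float* v, const float* g,
                             arma::uword n, float lr, float c1, float c2) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  for (arma::uword i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0f - b1) * g[i];
    v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

static void forward(const arma::fmat& X, const MatList& W, const VecList& b,
                    const std::vector<int>& relu, MatList& A) {
  A[0] = X;
  for (size_t l = 0; l < W.size(); ++l) {
    A[l + 1] = A[l] * W[l];
    bias_act(A[l + 1], b[l], relu[l]);
  }
}

static double full_mse(const arma::fmat& X, const MatList& W,
                       const VecList& b, const std::vector<int>& relu) {
  arma::fmat A = X;
  for (size_t l = 0; l < W.size(); ++l) {
    arma::fmat Z = A * W[l];
    bias_act(Z, b[l], relu[l]);
    A = std::move(Z);
  }
  const float* a = A.memptr();
  const float* x = X.memptr();
  double acc = 0.0;
  for (arma::uword i = 0; i < A.n_elem; ++i) {
    const double d = (double)a[i] - (double)x[i];
    acc += d * d;
  }
  return acc / A.n_elem;
}

// [[Rcpp::export(name = ".ae_train_cpp")]]
List ae_train_cpp(const arma::mat& X_, IntegerVector dims_,
                  IntegerVector relu_, int epochs, int batch_size,
                  double lr_, int patience, double rel_tol) {
  const int L = dims_.size() - 1;
  std::vector<int> dims(dims_.begin(), dims_.end());
  std::vector<int> relu(relu_.begin(), relu_.end());
  const arma::fmat X = arma::conv_to<arma::fmat>::from(X_);
  const int n = X.n_rows;
  const float lr = (float)lr_;

  // He / Xavier init, filled column-major from R's normal RNG
  MatList W(L);
  VecList b(L);
  for (int l = 0; l < L; ++l) {
    const double sd = relu[l] ? std::sqrt(2.0 / dims[l])
                              : std::sqrt(1.0 / dims[l]);
    W[l].set_size(dims[l], dims[l + 1]);
    for (int j = 0; j < dims[l + 1]; ++j)
      for (int i = 0; i < dims[l]; ++i)
        W[l](i, j) = (float)(norm_rand() * sd);
    b[l].zeros(dims[l + 1]);
  }

  MatList mW(L), vW(L), dW(L);
  VecList mb(L), vb(L), db(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(dims[l], dims[l + 1]);
    vW[l].zeros(dims[l], dims[l + 1]);
    dW[l].zeros(dims[l], dims[l + 1]);
    mb[l].zeros(dims[l + 1]);
    vb[l].zeros(dims[l + 1]);
    db[l].zeros(dims[l + 1]);
  }
  long t = 0;
  MatList A(L + 1);

  const double initial = full_mse(X, W, b, relu);
  double best = initial;
  int best_epoch = 0;
  MatList bestW = W;
  VecList bestb = b;
  std::vector<double> trace;
  trace.reserve(epochs);

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    IntegerVector ord = sample(n, n, false);  // R RNG, 1-based
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n) - 1;
      arma::uvec rows(e - s + 1);
      for (int i = s; i <= e; ++i) rows(i - s) = ord[i] - 1;
      const arma::fmat Xb = X.rows(rows);
      forward(Xb, W, b, relu, A);

      arma::fmat dA = (2.0f / (Xb.n_rows * Xb.n_cols)) * (A[L] - Xb);
      for (int l = L - 1; l >= 0; --l) {
        if (relu[l]) {  // dZ = dA masked by the activation, in place
          const float* act = A[l + 1].memptr();
          float* dz = dA.memptr();
          for (arma::uword i = 0; i < dA.n_elem; ++i)
            if (act[i] <= 0.0f) dz[i] = 0.0f;
        }
        dW[l] = A[l].t() * dA;
        db[l] = arma::sum(dA, 0);
        if (l > 0) dA = dA * W[l].t();
      }

      ++t;
      const float c1 = 1.0f - std::pow(0.9f, (float)t);
      const float c2 = 1.0f - std::pow(0.999f, (float)t);
      for (int l = 0; l < L; ++l) {
        adam_step(W[l].memptr(), mW[l].memptr(), vW[l].memptr(),
          dW[l].memptr(), W[l].n_elem, lr, c1, c2);
        adam_step(b[l].memptr(), mb[l].memptr(), vb[l].memptr(),
          db[l].memptr(), b[l].n_elem, lr, c1, c2);
      }
    }

    const double mse = full_mse(X, W, b, relu);
    trace.push_back(mse);
    if (!std::isfinite(mse)) {
      return List::create(_["error"] = epoch);
    }
    if (mse < best * (1.0 - rel_tol)) best_epoch = epoch;
    if (mse < best) {
      best = mse;
      bestW = W;
      bestb = b;
    }
    if (patience > 0 && epoch - best_epoch >= patience) break;
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = wrap(arma::conv_to<arma::mat>::from(bestW[l]));
    arma::rowvec bd = arma::conv_to<arma::rowvec>::from(bestb[l]);
    bout[l] = NumericVector(bd.begin(), bd.end());
  }
  return List::create(
    _["W"] = Wout, _["b"] = bout,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["initial_mse"] = initial, _["final_mse"] = best,
    _["epochs_run"] = (int)trace.size());
}
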