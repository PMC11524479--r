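// Minimal 1-D convolution / max-pooling kernels for the wingbeat CNN.
// Layout convention: activations are cubes (length, channels, batch);
// conv weights are matrices (kernel*in_channels, out_channels) with the
// row index c*K + k (channel-major, then tap), biases are vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_len(int L, int K, int stride, int pad) {
  return (L + 2 * pad - K) / stride + 1;
}

// im2col for one example: (P x K*C_in), zero-padded outside [0, L)
static mat im2col1d(const mat &x, int K, int stride, int pad, int P) {
  const int L = x.n_rows, C = x.n_cols;
  mat cols(P, K * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int j = c * K + k;
      for (int p = 0; p < P; ++p) {
        const int t = p * stride + k - pad;
        if (t >= 0 && t < L) cols(p, j) = x(t, c);
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube &X, const arma::mat &W,
                      const arma::vec &b, int stride, int pad) {
  const int L = X.n_rows, N = X.n_slices;
  const int C_out = W.n_cols;
  const int K = W.n_rows / X.n_cols;
  const int P = out_len(L, K, stride, pad);
  if (P < 1) Rcpp::stop("conv1d: output length < 1 (input %d, kernel %d, stride %d)", L, K, stride);
  cube Y(P, C_out, N);
  for (int n = 0; n < N; ++n) {
    mat cols = im2col1d(X.slice(n), K, stride, pad, P);
    Y.slice(n) = cols * W;
    Y.slice(n).each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube &X, const arma::mat &W,
                      const arma::cube &dY, int stride, int pad) {
  const int L = X.n_rows, C_in = X.n_cols, N = X.n_slices;
  const int K = W.n_rows / C_in;
  const int P = dY.n_rows;
  cube dX(L, C_in, N, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_cols, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat cols = im2col1d(X.slice(n), K, stride, pad, P);
    dW += cols.t() * dY.slice(n);
    db += sum(dY.slice(n), 0).t();
    mat dcols = dY.slice(n) * W.t();  // (P x K*C_in)
    for (int c = 0; c < C_in; ++c) {
      for (int k = 0; k < K; ++k) {
        const int j = c * K + k;
        for (int p = 0; p < P; ++p) {
          const int t = p * stride + k - pad;
          if (t >= 0 && t < L) dX(t, c, n) += dcols(p, j);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool1d_fwd(const arma::cube &X, int pool) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int P = L / pool;  // trailing remainder dropped
  if (P < 1) Rcpp::stop("maxpool1d: output length < 1");
  cube Y(P, C, N);
  ucube idx(P, C, N);  // argmax position in the input, 0-based
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      for (int p = 0; p < P; ++p) {
        int best = p * pool;
        double v = X(best, c, n);
        for (int k = 1; k < pool; ++k) {
          const int t = p * pool + k;
          if (X(t, c, n) > v) { v = X(t, c, n); best = t; }
        }
        Y(p, c, n) = v;
        idx(p, c, n) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool1d_bwd(const arma::ucube &idx, const arma::cube &dY, int L) {
  const int P = dY.n_rows, C = dY.n_cols, N = dY.n_slices;
  cube dX(L, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int p = 0; p < P; ++p)
        dX(idx(p, c, n), c, n) += dY(p, c, n);
  return dX;
}
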