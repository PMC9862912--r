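// Shallow ConvNet compute kernels.
//
// Layer chain (valid convolutions throughout):
//   input  L0 x c            (time x channels, one crop)
//   temporal conv   K x 1, F filters, time stride `stride`  -> L1 x c x F
//   spatial  conv   1 x c over all channels & input maps    -> L1 x F
//   batch norm (per map) -> square -> average pool (avg_len, stride 1)
//   -> max pool (max_len, stride max_stride) -> log -> dense -> softmax
//
// Batches are cubes with time on rows, channels on columns, crops on
// slices.  The temporal-conv output is flattened to L1 x (c*F) with
// column index  f*c + ch  (channel fastest) so the spatial convolution
// is a single GEMM against Ws ((c*F) x F).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline void check_arch(int L0, int c, int K, int F, int stride,
                              int avg_len, int max_len, int max_stride,
                              const mat& Ws, const mat& Wd, int& L1,
                              int& L2, int& L3, int& densein) {
  if (L0 < K) Rcpp::stop("input shorter than temporal filter");
  L1 = (L0 - K) / stride + 1;
  if (L1 < avg_len) Rcpp::stop("temporal-conv output shorter than average-pool window");
  L2 = L1 - avg_len + 1;
  if (L2 < max_len) Rcpp::stop("average-pool output shorter than max-pool window");
  L3 = (L2 - max_len) / max_stride + 1;
  densein = L3 * F;
  if ((int)Ws.n_rows != c * F || (int)Ws.n_cols != F)
    Rcpp::stop("spatial weight shape mismatch");
  if ((int)Wd.n_rows != densein)
    Rcpp::stop("dense weight rows (%d) do not match flattened features (%d)",
               (int)Wd.n_rows, densein);
}

// strided copy of one channel: S(i, k) = X(i*stride + k, ch)
static inline void im2col_time(const mat& X, int ch, int K, int stride,
                               int L1, mat& S) {
  for (int k = 0; k < K; ++k) {
    const double* src = X.colptr(ch) + k;
    double* dst = S.colptr(k);
    for (int i = 0; i < L1; ++i) dst[i] = src[i * stride];
  }
}

// average pool window avg_len, stride 1, via cumulative sums (per column)
static inline mat avgpool(const mat& A, int avg_len, int L2) {
  mat P(L2, A.n_cols);
  vec cs(A.n_rows + 1);
  for (uword m = 0; m < A.n_cols; ++m) {
    cs[0] = 0.0;
    const double* a = A.colptr(m);
    for (uword i = 0; i < A.n_rows; ++i) cs[i + 1] = cs[i] + a[i];
    double* p = P.colptr(m);
    for (int i = 0; i < L2; ++i) p[i] = (cs[i + avg_len] - cs[i]) / avg_len;
  }
  return P;
}

// scatter average-pool gradient back: dA(r) = sum over windows covering r / avg_len
static inline mat avgpool_back(const mat& dP, int avg_len, int L1) {
  mat dA(L1, dP.n_cols, fill::zeros);
  // window i covers rows [i, i+avg_len); accumulate via difference array
  for (uword m = 0; m < dP.n_cols; ++m) {
    vec diff(L1 + 1, fill::zeros);
    const double* dp = dP.colptr(m);
    for (uword i = 0; i < dP.n_rows; ++i) {
      diff[i] += dp[i];
      diff[i + avg_len] -= dp[i];
    }
    double run = 0.0;
    double* da = dA.colptr(m);
    for (int r = 0; r < L1; ++r) {
      run += diff[r];
      da[r] = run / avg_len;
    }
  }
  return dA;
}

static inline void softmax_rows(mat& logits) {
  for (uword i = 0; i < logits.n_rows; ++i) {
    rowvec r = logits.row(i);
    r -= r.max();
    rowvec e = exp(r);
    logits.row(i) = e / accu(e);
  }
}

// Inference-mode forward pass: batch-norm uses running statistics, no
// dropout.  Returns B x s class-score matrix (softmax rows).
// [[Rcpp::export]]
arma::mat scnn_forward_cpp(const arma::cube& x, const arma::mat& Wt,
                           const arma::mat& Ws, const arma::vec& gamma,
                           const arma::vec& beta, const arma::mat& Wd,
                           const arma::vec& bd, const arma::vec& bn_mean,
                           const arma::vec& bn_var, int stride, int avg_len,
                           int max_len, int max_stride, double bn_eps,
                           double log_eps) {
  const int L0 = x.n_rows, c = x.n_cols, B = x.n_slices;
  const int K = Wt.n_rows, F = Wt.n_cols;
  int L1, L2, L3, densein;
  check_arch(L0, c, K, F, stride, avg_len, max_len, max_stride, Ws, Wd,
             L1, L2, L3, densein);

  mat logits(B, Wd.n_cols);
  mat S(L1, K), T1(L1, c * F), Z, Y(L1, F), A, P, G(L3, F);
  vec inv_sd = 1.0 / sqrt(bn_var + bn_eps);
  for (int b = 0; b < B; ++b) {
    const mat& X = x.slice(b);
    for (int ch = 0; ch < c; ++ch) {
      im2col_time(X, ch, K, stride, L1, S);
      mat R = S * Wt;  // L1 x F
      for (int f = 0; f < F; ++f) T1.col(f * c + ch) = R.col(f);
    }
    Z = T1 * Ws;  // L1 x F
    for (int m = 0; m < F; ++m)
      Y.col(m) = gamma[m] * ((Z.col(m) - bn_mean[m]) * inv_sd[m]) + beta[m];
    A = square(Y);
    P = avgpool(A, avg_len, L2);
    for (int t = 0; t < L3; ++t)
      for (int m = 0; m < F; ++m) {
        double v = P(span(t * max_stride, t * max_stride + max_len - 1), span(m, m)).max();
        G(t, m) = std::log(std::max(v, log_eps));
      }
    vec fv = vectorise(G);  // densein (column-major: time fastest)
    logits.row(b) = (Wd.t() * fv + bd).t();
  }
  softmax_rows(logits);
  return logits;
}

// Training-mode forward + backward.  Batch norm uses batch statistics
// (biased variance) and reports updated running statistics.  `drop_mask`
// (length densein) is an inverted-dropout mask including the 1/(1-p)
// scaling, or length 0 for no dropout.  Labels are 1-based.
// [[Rcpp::export]]
Rcpp::List scnn_train_step_cpp(const arma::cube& x, const arma::uvec& y,
                               const arma::mat& Wt, const arma::mat& Ws,
                               const arma::vec& gamma, const arma::vec& beta,
                               const arma::mat& Wd, const arma::vec& bd,
                               const arma::vec& bn_mean, const arma::vec& bn_var,
                               const arma::vec& drop_mask, int stride,
                               int avg_len, int max_len, int max_stride,
                               double bn_eps, double log_eps,
                               double bn_momentum) {
  const int L0 = x.n_rows, c = x.n_cols, B = x.n_slices;
  const int K = Wt.n_rows, F = Wt.n_cols, s = Wd.n_cols;
  int L1, L2, L3, densein;
  check_arch(L0, c, K, F, stride, avg_len, max_len, max_stride, Ws, Wd,
             L1, L2, L3, densein);
  if ((int)y.n_elem != B) Rcpp::stop("label/batch size mismatch");
  const bool dropout = drop_mask.n_elem > 0;
  if (dropout && (int)drop_mask.n_elem != densein)
    Rcpp::stop("dropout mask length mismatch");

  // ---- forward ----
  cube T1(L1, c * F, B), Xhat(L1, F, B), Pmax(L3, F, B);
  ucube argmx(L3, F, B);
  mat fvecs(densein, B), S(L1, K);

  // temporal + spatial conv
  cube Z(L1, F, B);
  for (int b = 0; b < B; ++b) {
    const mat& X = x.slice(b);
    for (int ch = 0; ch < c; ++ch) {
      im2col_time(X, ch, K, stride, L1, S);
      mat R = S * Wt;
      for (int f = 0; f < F; ++f) T1.slice(b).col(f * c + ch) = R.col(f);
    }
    Z.slice(b) = T1.slice(b) * Ws;
  }

  // batch norm statistics across time x batch, per map
  const double N = (double)L1 * B;
  vec mu(F, fill::zeros), var(F, fill::zeros);
  for (int m = 0; m < F; ++m) {
    double sum = 0.0, sum2 = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* z = Z.slice(b).colptr(m);
      for (int i = 0; i < L1; ++i) { sum += z[i]; sum2 += z[i] * z[i]; }
    }
    mu[m] = sum / N;
    var[m] = std::max(sum2 / N - mu[m] * mu[m], 0.0);
  }
  vec inv_sd = 1.0 / sqrt(var + bn_eps);

  mat logits(B, s);
  for (int b = 0; b < B; ++b) {
    mat Y(L1, F);
    for (int m = 0; m < F; ++m) {
      Xhat.slice(b).col(m) = (Z.slice(b).col(m) - mu[m]) * inv_sd[m];
      Y.col(m) = gamma[m] * Xhat.slice(b).col(m) + beta[m];
    }
    mat P = avgpool(square(Y), avg_len, L2);
    mat G(L3, F);
    for (int t = 0; t < L3; ++t)
      for (int m = 0; m < F; ++m) {
        uword rel;
        double v = P(span(t * max_stride, t * max_stride + max_len - 1),
                     span(m, m)).max(rel);
        argmx(t, m, b) = t * max_stride + rel;
        Pmax(t, m, b) = v;
        G(t, m) = std::log(std::max(v, log_eps));
      }
    vec fv = vectorise(G);
    if (dropout) fv %= drop_mask;
    fvecs.col(b) = fv;
    logits.row(b) = (Wd.t() * fv + bd).t();
  }
  softmax_rows(logits);

  double loss = 0.0;
  int n_correct = 0;
  for (int b = 0; b < B; ++b) {
    loss -= std::log(std::max(logits(b, y[b] - 1), 1e-300));
    if ((uword)logits.row(b).index_max() == y[b] - 1) ++n_correct;
  }
  loss /= B;

  // ---- backward ----
  mat dlogits = logits;  // B x s
  for (int b = 0; b < B; ++b) dlogits(b, y[b] - 1) -= 1.0;
  dlogits /= B;

  mat dWd = fvecs * dlogits;        // densein x s
  vec dbd = sum(dlogits, 0).t();

  mat dWt(K, F, fill::zeros), dWs(c * F, F, fill::zeros);
  vec dgamma(F, fill::zeros), dbeta(F, fill::zeros);

  // per-map accumulators for batch-norm backward
  vec sum_dxhat(F, fill::zeros), sum_dxhat_xhat(F, fill::zeros);
  cube dY(L1, F, B);

  for (int b = 0; b < B; ++b) {
    vec dfv = Wd * dlogits.row(b).t();  // densein
    if (dropout) dfv %= drop_mask;
    mat dG(L3, F);
    std::memcpy(dG.memptr(), dfv.memptr(), sizeof(double) * densein);
    mat dP(L2, F, fill::zeros);
    for (int t = 0; t < L3; ++t)
      for (int m = 0; m < F; ++m) {
        double v = Pmax(t, m, b);
        if (v > log_eps)  // clamped values have zero gradient
          dP(argmx(t, m, b), m) += dG(t, m) / v;
      }
    mat dA = avgpool_back(dP, avg_len, L1);
    for (int m = 0; m < F; ++m) {
      vec Ym = gamma[m] * Xhat.slice(b).col(m) + beta[m];
      vec dYm = 2.0 * (Ym % dA.col(m));
      dY.slice(b).col(m) = dYm;
      dbeta[m] += accu(dYm);
      dgamma[m] += dot(dYm, Xhat.slice(b).col(m));
      sum_dxhat[m] += gamma[m] * accu(dYm);
      sum_dxhat_xhat[m] += gamma[m] * dot(dYm, Xhat.slice(b).col(m));
    }
  }

  for (int b = 0; b < B; ++b) {
    mat dZ(L1, F);
    for (int m = 0; m < F; ++m) {
      vec dxhat = gamma[m] * dY.slice(b).col(m);
      dZ.col(m) = inv_sd[m] * (dxhat - sum_dxhat[m] / N -
                               Xhat.slice(b).col(m) * (sum_dxhat_xhat[m] / N));
    }
    dWs += T1.slice(b).t() * dZ;
    mat dT1 = dZ * Ws.t();  // L1 x c*F
    const mat& X = x.slice(b);
    for (int ch = 0; ch < c; ++ch) {
      mat dR(L1, F);
      for (int f = 0; f < F; ++f) dR.col(f) = dT1.col(f * c + ch);
      im2col_time(X, ch, K, stride, L1, S);
      dWt += S.t() * dR;
    }
  }

  vec new_mean = (1.0 - bn_momentum) * bn_mean + bn_momentum * mu;
  vec new_var = (1.0 - bn_momentum) * bn_var + bn_momentum * var;

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("n_correct") = n_correct,
      Rcpp::Named("probs") = logits,
      Rcpp::Named("dWt") = dWt, Rcpp::Named("dWs") = dWs,
      Rcpp::Named("dgamma") = dgamma, Rcpp::Named("dbeta") = dbeta,
      Rcpp::Named("dWd") = dWd, Rcpp::Named("dbd") = dbd,
      Rcpp::Named("bn_mean") = new_mean, Rcpp::Named("bn_var") = new_var);
}

// Electrode-wise exponential moving standardization with +/- clip*sigma
// outlier rectification.  Per sample (in order): clip with the previous
// step's statistics, update mean then variance with the clipped value,
// emit (clipped - mean) / sd using the updated statistics.
// [[Rcpp::export]]
arma::vec ems_channel_cpp(const arma::vec& x, double mu0, double var0,
                          double lambda, double clip, double var_floor) {
  const int n = x.n_elem;
  vec out(n);
  double mu = mu0, var = std::max(var0, var_floor);
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(var);
    double xi = std::min(std::max(x[i], mu - clip * sd), mu + clip * sd);
    mu = lambda * mu + (1.0 - lambda) * xi;
    var = lambda * var + (1.0 - lambda) * (xi - mu) * (xi - mu);
    out[i] = (xi - mu) / std::sqrt(std::max(var, var_floor));
  }
  return out;
}
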