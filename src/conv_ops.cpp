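// Compute kernels for the neural-network engine.
//
// Feature tensors are (N x B) matrices in channel-fastest layout
// (row = (spatial - 1) * C + c, spatial column-major): with it the GEMM
// output (C_out x P*B) *is* the next layer's input after a zero-copy
// reshape, so no array permutes are ever needed. Convolutions run as one
// full-size BLAS dgemm per layer over an im2col patch matrix kept in a
// persistent workspace (reused across calls, so its pages stay warm);
// `gather` maps patch entry (p-1)*K + kk (1-based) to its input row, with
// sentinel N+1 standing for a zero padding pixel. Batch normalisation is
// fused with its activation.

#include <Rcpp.h>
#include <algorithm>
#ifndef USE_FC_LEN_T
#define USE_FC_LEN_T
#endif
#include <R_ext/BLAS.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

static inline NumericMatrix alloc_noinit(int nr, int nc) {
  NumericMatrix out(Rf_allocMatrix(REALSXP, nr, nc));
  return out;
}

// persistent patch workspaces (single-threaded R; grown monotonically)
static std::vector<double> ws1, ws2;

static inline double* workspace(std::vector<double>& ws, size_t need) {
  if (ws.size() < need) ws.resize(need);
  return ws.data();
}

// Keep large freed buffers on the process heap instead of returning them to
// the OS: the training loop allocates fixed-size tensors every step and
// re-faulting fresh pages can dominate runtime.
// [[Rcpp::export]]
void cpp_tune_alloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// build the full (K x P*B) patch matrix into `buf`
static void im2col_into(const double* __restrict x, const int* __restrict g,
                        int N, int B, int PK, double* __restrict buf) {
  for (int b = 0; b < B; ++b) {
    const double* __restrict xb = x + (size_t)N * b;
    double* __restrict ob = buf + (size_t)PK * b;
    for (int r = 0; r < PK; ++r) {
      const int gi = g[r];
      ob[r] = (gi <= N) ? xb[gi - 1] : 0.0;
    }
  }
}

// scatter-add the (K x P*B) patch matrix in `buf` onto (N x B) `out`
static void col2im_onto(const double* __restrict buf, const int* __restrict g,
                        int N, int B, int PK, double* __restrict out) {
  for (int b = 0; b < B; ++b) {
    const double* __restrict pb = buf + (size_t)PK * b;
    double* __restrict ob = out + (size_t)N * b;
    for (int r = 0; r < PK; ++r) {
      const int gi = g[r];
      if (gi <= N) ob[gi - 1] += pb[r];
    }
  }
}

// standalone im2col, used by tests as an independent reference path
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerVector& gather,
                         int K) {
  const int B = X.ncol(), N = X.nrow(), PK = gather.size();
  NumericMatrix out = alloc_noinit(K, (PK / K) * B);
  im2col_into(X.begin(), gather.begin(), N, B, PK, out.begin());
  return out;
}

// standalone col2im (adjoint scatter-add): dP (P*K x B) -> dX (N x B)
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dP, const IntegerVector& gather,
                         int N) {
  NumericMatrix out(N, dP.ncol());
  col2im_onto(dP.begin(), gather.begin(), N, dP.ncol(), gather.size(),
              out.begin());
  return out;
}

// fill (Cout*P x B) matrix with a per-channel constant, channel-fastest
static void fill_channel(double* __restrict o, size_t n,
                         const double* __restrict v, int C) {
  for (size_t i = 0; i < n;)
    for (int c = 0; c < C; ++c, ++i) o[i] = v[c];
}

// conv forward: out (Cout*P x B) = W (Cout x K) * patches(X) + bias
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& X, const IntegerVector& gather,
                           const NumericMatrix& W, const NumericVector& bias) {
  const int N = X.nrow(), B = X.ncol();
  const int Cout = W.nrow(), K = W.ncol();
  const int PK = gather.size(), P = PK / K;
  double* buf = workspace(ws1, (size_t)PK * B);
  im2col_into(X.begin(), gather.begin(), N, B, PK, buf);
  NumericMatrix out = alloc_noinit(Cout * P, B);
  fill_channel(out.begin(), (size_t)Cout * P * B, bias.begin(), Cout);
  const double one = 1.0;
  const int PB = P * B;
  F77_CALL(dgemm)("N", "N", &Cout, &PB, &K, &one, W.begin(), &Cout,
                  buf, &K, &one, out.begin(), &Cout FCONE FCONE);
  return out;
}

// conv backward: given dZ (Cout*P x B) and cached input X, returns
// dX = col2im(W^T dZ), dW = dZ patches(X)^T, db = channel sums of dZ
// [[Rcpp::export]]
List cpp_conv_bwd(const NumericMatrix& dZ, const NumericMatrix& X,
                  const IntegerVector& gather, const NumericMatrix& W,
                  bool want_dx) {
  const int N = X.nrow(), B = X.ncol();
  const int Cout = W.nrow(), K = W.ncol();
  const int PK = gather.size(), P = PK / K, PB = P * B;
  const double one = 1.0, zero = 0.0;
  double* buf = workspace(ws1, (size_t)PK * B);
  im2col_into(X.begin(), gather.begin(), N, B, PK, buf);
  NumericMatrix dW(Cout, K);
  F77_CALL(dgemm)("N", "T", &Cout, &K, &PB, &one, dZ.begin(), &Cout,
                  buf, &K, &zero, dW.begin(), &Cout FCONE FCONE);
  NumericVector db(Cout);
  {
    const double* __restrict z = dZ.begin();
    double* __restrict d = db.begin();
    const size_t n = (size_t)Cout * PB;
    for (size_t i = 0; i < n;)
      for (int c = 0; c < Cout; ++c, ++i) d[c] += z[i];
  }
  NumericMatrix dX(want_dx ? N : 1, want_dx ? B : 1);
  if (want_dx) {
    double* pbuf = workspace(ws2, (size_t)PK * B);
    F77_CALL(dgemm)("T", "N", &K, &PB, &Cout, &one, W.begin(), &Cout,
                    dZ.begin(), &Cout, &zero, pbuf, &K FCONE FCONE);
    col2im_onto(pbuf, gather.begin(), N, B, PK, dX.begin());
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// transposed-conv forward: out (N x B) = col2im(W^T X) + bias,
// X is (Cin*P x B), W is (Cin x K), N the upsampled size, bias per output
// channel (recycled channel-fastest).
// [[Rcpp::export]]
NumericMatrix cpp_tconv_fwd(const NumericMatrix& X, const IntegerVector& gather,
                            const NumericMatrix& W, const NumericVector& bias,
                            int N) {
  const int B = X.ncol();
  const int Cin = W.nrow(), K = W.ncol();
  const int PK = gather.size(), P = PK / K, PB = P * B;
  const double one = 1.0, zero = 0.0;
  double* pbuf = workspace(ws1, (size_t)PK * B);
  F77_CALL(dgemm)("T", "N", &K, &PB, &Cin, &one, W.begin(), &Cin,
                  X.begin(), &Cin, &zero, pbuf, &K FCONE FCONE);
  NumericMatrix out = alloc_noinit(N, B);
  fill_channel(out.begin(), (size_t)N * B, bias.begin(), bias.size());
  col2im_onto(pbuf, gather.begin(), N, B, PK, out.begin());
  return out;
}

// transposed-conv backward: dXin = W patches(dY), dW = Xin patches(dY)^T,
// db = per-output-channel sums of dY
// [[Rcpp::export]]
List cpp_tconv_bwd(const NumericMatrix& dY, const NumericMatrix& Xin,
                   const IntegerVector& gather, const NumericMatrix& W,
                   int Cout) {
  const int N = dY.nrow(), B = dY.ncol();
  const int Cin = W.nrow(), K = W.ncol();
  const int PK = gather.size(), P = PK / K, PB = P * B;
  const double one = 1.0, zero = 0.0;
  double* buf = workspace(ws1, (size_t)PK * B);
  im2col_into(dY.begin(), gather.begin(), N, B, PK, buf);
  NumericMatrix dXin = alloc_noinit(Cin * P, B);
  F77_CALL(dgemm)("N", "N", &Cin, &PB, &K, &one, W.begin(), &Cin,
                  buf, &K, &zero, dXin.begin(), &Cin FCONE FCONE);
  NumericMatrix dW(Cin, K);
  F77_CALL(dgemm)("N", "T", &Cin, &K, &PB, &one, Xin.begin(), &Cin,
                  buf, &K, &zero, dW.begin(), &Cin FCONE FCONE);
  NumericVector db(Cout);
  {
    const double* __restrict y = dY.begin();
    double* __restrict d = db.begin();
    const size_t n = (size_t)N * B;
    for (size_t i = 0; i < n;)
      for (int c = 0; c < Cout; ++c, ++i) d[c] += y[i];
  }
  return List::create(_["dX"] = dXin, _["dW"] = dW, _["db"] = db);
}

// ---- batch normalisation (optionally fused with leaky-ReLU) ----------------

// per-channel mean and (biased) variance, channel-fastest layout
// [[Rcpp::export]]
List cpp_bn_stats(const NumericMatrix& X, int groups) {
  const size_t n = (size_t)X.nrow() * X.ncol();
  const size_t m = n / groups;
  std::vector<double> mu(groups, 0.0), m2(groups, 0.0);
  const double* __restrict x = X.begin();
  double* __restrict mup = mu.data();
  double* __restrict m2p = m2.data();
  for (size_t i = 0; i < n;) {
    for (int c = 0; c < groups; ++c, ++i) {
      const double v = x[i];
      mup[c] += v;
      m2p[c] += v * v;
    }
  }
  NumericVector mean(groups), var(groups);
  for (int c = 0; c < groups; ++c) {
    mean[c] = mu[c] / m;
    const double va = m2[c] / m - mean[c] * mean[c];
    var[c] = va > 0 ? va : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = act(x * a + c); act: alpha = 1 -> identity, else leaky ReLU slope alpha
// (alpha = 0 is plain ReLU); a, c recycled channel-fastest
// [[Rcpp::export]]
NumericMatrix cpp_scale_shift_act(const NumericMatrix& X,
                                  const NumericVector& a,
                                  const NumericVector& c, double alpha) {
  const int groups = a.size();
  const size_t n = (size_t)X.nrow() * X.ncol();
  NumericMatrix out = alloc_noinit(X.nrow(), X.ncol());
  const double* __restrict x = X.begin();
  double* __restrict o = out.begin();
  std::vector<double> av(a.begin(), a.end()), cv(c.begin(), c.end());
  const double* __restrict ap = av.data();
  const double* __restrict cp = cv.data();
  if (alpha == 1.0) {
    for (size_t i = 0; i < n;)
      for (int g = 0; g < groups; ++g, ++i) o[i] = x[i] * ap[g] + cp[g];
  } else {
    for (size_t i = 0; i < n;) {
      for (int g = 0; g < groups; ++g, ++i) {
        const double v = x[i] * ap[g] + cp[g];
        o[i] = std::max(v, 0.0) + alpha * std::min(v, 0.0);
      }
    }
  }
  return out;
}

// fused batch-norm(+activation) backward: X is the bn input, `out` the
// (activated) layer output, dY the upstream gradient. Returns dX, dgamma,
// dbeta. alpha = 1 -> no activation; else leaky ReLU slope alpha.
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& X, const NumericMatrix& dY,
                const NumericMatrix& out,
                const NumericVector& mu, const NumericVector& inv_sd,
                const NumericVector& gamma, double alpha, bool training) {
  const int gr = mu.size();
  const size_t n = (size_t)X.nrow() * X.ncol();
  const double m = (double)n / gr;
  const double* __restrict x = X.begin();
  const double* __restrict dy = dY.begin();
  const double* __restrict op = out.begin();
  std::vector<double> muv(mu.begin(), mu.end()),
      ivv(inv_sd.begin(), inv_sd.end()), gav(gamma.begin(), gamma.end());
  const double* __restrict mup = muv.data();
  const double* __restrict ivp = ivv.data();
  const double* __restrict gap = gav.data();
  const bool act = alpha != 1.0;
  std::vector<double> s1(gr, 0.0), s2(gr, 0.0);
  {
    double* __restrict s1p = s1.data();
    double* __restrict s2p = s2.data();
    for (size_t i = 0; i < n;) {
      for (int g = 0; g < gr; ++g, ++i) {
        double dz = dy[i];
        if (act && op[i] <= 0) dz *= alpha;
        s1p[g] += dz;
        s2p[g] += dz * (x[i] - mup[g]) * ivp[g];
      }
    }
  }
  NumericMatrix dX = alloc_noinit(X.nrow(), X.ncol());
  double* __restrict r = dX.begin();
  if (training) {
    std::vector<double> u(gr), c1(gr), c2(gr);
    for (int g = 0; g < gr; ++g) {
      u[g] = gav[g] * ivv[g];
      c1[g] = u[g] * s1[g] / m;
      c2[g] = u[g] * s2[g] / m;
    }
    const double* __restrict up = u.data();
    const double* __restrict c1p = c1.data();
    const double* __restrict c2p = c2.data();
    for (size_t i = 0; i < n;) {
      for (int g = 0; g < gr; ++g, ++i) {
        double dz = dy[i];
        if (act && op[i] <= 0) dz *= alpha;
        const double xh = (x[i] - mup[g]) * ivp[g];
        r[i] = up[g] * dz - c1p[g] - xh * c2p[g];
      }
    }
  } else {
    for (size_t i = 0; i < n;) {
      for (int g = 0; g < gr; ++g, ++i) {
        double dz = dy[i];
        if (act && op[i] <= 0) dz *= alpha;
        r[i] = gap[g] * ivp[g] * dz;
      }
    }
  }
  NumericVector dgamma(gr), dbeta(gr);
  for (int g = 0; g < gr; ++g) { dgamma[g] = s2[g]; dbeta[g] = s1[g]; }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- misc elementwise -------------------------------------------------------

// leaky ReLU forward (slope alpha)
// [[Rcpp::export]]
NumericMatrix cpp_lrelu(const NumericMatrix& X, double alpha) {
  NumericMatrix out = alloc_noinit(X.nrow(), X.ncol());
  const size_t n = (size_t)X.nrow() * X.ncol();
  const double* __restrict x = X.begin();
  double* __restrict o = out.begin();
  for (size_t i = 0; i < n; ++i)
    o[i] = std::max(x[i], 0.0) + alpha * std::min(x[i], 0.0);
  return out;
}

// dX = dY * (out > 0 ? 1 : alpha); `out` carries the sign of the input
// [[Rcpp::export]]
NumericMatrix cpp_lrelu_grad(const NumericMatrix& dY, const NumericMatrix& out,
                             double alpha) {
  NumericMatrix dX = alloc_noinit(dY.nrow(), dY.ncol());
  const size_t n = (size_t)dY.nrow() * dY.ncol();
  const double* __restrict d = dY.begin();
  const double* __restrict o = out.begin();
  double* __restrict r = dX.begin();
  for (size_t i = 0; i < n; ++i) {
    const double w = o[i] > 0 ? 1.0 : alpha;
    r[i] = w * d[i];
  }
  return dX;
}

// in-place Adam update: p, m, v are modified; caller owns them exclusively
// [[Rcpp::export]]
void cpp_adam(NumericVector p, NumericVector m, NumericVector v,
              const NumericVector& g, double lr, double beta1, double beta2,
              double bc1, double bc2, double eps) {
  const size_t n = p.size();
  double* __restrict pp = p.begin();
  double* __restrict mp = m.begin();
  double* __restrict vp = v.begin();
  const double* __restrict gp = g.begin();
  for (size_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}
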