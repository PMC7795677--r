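#include <Rcpp.h>
using namespace Rcpp;

// Same-padded batched temporal convolution: Z[i, t] = sum_a k[a] * Y[i, t + a - 1 - pad]
// (1-based formula; out-of-range taps contribute zero). With adjoint = true the
// transpose operator is applied, as needed for backpropagation.
// [[Rcpp::export]]
NumericMatrix conv_band_apply(const NumericMatrix& Y, const NumericVector& k,
                              int pad, bool adjoint) {
  const int n = Y.nrow(), L = Y.ncol(), c = k.size();
  NumericMatrix Z(n, L);
  for (int a = 0; a < c; ++a) {
    const int d = a - pad;             // source column offset (0-based)
    const double ka = k[a];
    if (ka == 0.0) continue;
    if (!adjoint) {
      // Z[, t] += k[a] * Y[, t + d]
      const int t0 = std::max(0, -d), t1 = std::min(L, L - d);
      for (int t = t0; t < t1; ++t) {
        const double* __restrict ysrc = &Y(0, t + d);
        double* __restrict zdst = &Z(0, t);
        for (int i = 0; i < n; ++i) zdst[i] += ka * ysrc[i];
      }
    } else {
      // Z[, t + d] += k[a] * Y[, t]
      const int t0 = std::max(0, -d), t1 = std::min(L, L - d);
      for (int t = t0; t < t1; ++t) {
        const double* __restrict ysrc = &Y(0, t);
        double* __restrict zdst = &Z(0, t + d);
        for (int i = 0; i < n; ++i) zdst[i] += ka * ysrc[i];
      }
    }
  }
  return Z;
}

// Gradient of the convolution with respect to the kernel:
// dk[a] = sum_{i, t} Y[i, t + a - 1 - pad] * dZ[i, t]
// [[Rcpp::export]]
NumericVector conv_kernel_grad_cpp(const NumericMatrix& Y, const NumericMatrix& dZ,
                                   int c, int pad) {
  const int n = Y.nrow(), L = Y.ncol();
  NumericVector dk(c);
  for (int a = 0; a < c; ++a) {
    const int d = a - pad;
    const int t0 = std::max(0, -d), t1 = std::min(L, L - d);
    double acc = 0.0;
    for (int t = t0; t < t1; ++t) {
      const double* __restrict ysrc = &Y(0, t + d);
      const double* __restrict zsrc = &dZ(0, t);
      for (int i = 0; i < n; ++i) acc += ysrc[i] * zsrc[i];
    }
    dk[a] = acc;
  }
  return dk;
}

static inline void conv_add(const double* Y, double* Z, const double* k,
                            int n, int L, int c, int pad, bool adjoint) {
  // destination-outer: each output column is accumulated over all taps in
  // one pass, so it is written once (sources stay cache-resident)
  for (int t = 0; t < L; ++t) {
    double* __restrict dst = Z + (size_t)n * t;
    for (int a = 0; a < c; ++a) {
      // forward: dst t reads source t + (a - pad); adjoint: source t - (a - pad)
      const int s = adjoint ? (t - (a - pad)) : (t + (a - pad));
      if (s < 0 || s >= L) continue;
      const double ka = k[a];
      if (ka == 0.0) continue;
      const double* __restrict src = Y + (size_t)n * s;
      for (int i = 0; i < n; ++i) dst[i] += ka * src[i];
    }
  }
}

static inline void conv_kgrad(const double* Y, const double* dZ, double* dk,
                              int n, int L, int c, int pad) {
  for (int a = 0; a < c; ++a) {
    const int d = a - pad;
    const int t0 = std::max(0, -d), t1 = std::min(L, L - d);
    double acc = 0.0;
    for (int t = t0; t < t1; ++t) {
      const double* __restrict ysrc = Y + (size_t)n * (t + d);
      const double* __restrict zsrc = dZ + (size_t)n * t;
      for (int i = 0; i < n; ++i) acc += ysrc[i] * zsrc[i];
    }
    dk[a] += acc;
  }
}

// One fused training step of the two-layer convolutional autoencoder:
// forward pass, binary cross-entropy loss and all weight gradients for a
// minibatch. X is the n x (L*C) channel-stacked instance matrix.
// [[Rcpp::export]]
List ae_batch_step_cpp(const NumericMatrix& X, int L, int C,
                       const NumericVector& w1, double b1,
                       const NumericMatrix& k2, const NumericVector& b2,
                       const NumericVector& kd, const NumericVector& bd,
                       int pad) {
  const int n = X.nrow();
  const int c = k2.nrow(), nf = k2.ncol();
  const size_t nl = (size_t)n * L;
  const double eps = 1e-7;
  const double invN = 1.0 / ((double)n * L * C);

  std::vector<double> Y(nl, 0.0);
  // channel fusion: Y = b1 + sum_c w1[c] * X_c
  for (int ch = 0; ch < C; ++ch) {
    const double wc = w1[ch];
    const double* __restrict xc = &X(0, ch * L);
    for (size_t s = 0; s < nl; ++s) Y[s] += wc * xc[s];
  }
  for (size_t s = 0; s < nl; ++s) Y[s] += b1;

  std::vector<std::vector<double>> Zpre(nf), Z(nf), dZ(nf);
  for (int f = 0; f < nf; ++f) {
    Zpre[f].assign(nl, 0.0);
    conv_add(Y.data(), Zpre[f].data(), &k2(0, f), n, L, c, pad, false);
    const double bf = b2[f];
    Z[f].resize(nl);
    for (size_t s = 0; s < nl; ++s) {
      const double v = Zpre[f][s] + bf;
      Zpre[f][s] = v;
      Z[f][s] = v > 0.0 ? v : 0.0;
    }
    dZ[f].assign(nl, 0.0);
  }

  NumericVector gw1(C), gk2(c * nf), gb2(nf), gkd(c * nf * C), gbd(C);
  double gb1 = 0.0, loss = 0.0;

  std::vector<double> P(nl), dP(nl);
  for (int j = 0; j < C; ++j) {
    std::fill(P.begin(), P.end(), bd[j]);
    for (int f = 0; f < nf; ++f) {
      conv_add(Z[f].data(), P.data(), &kd[(size_t)c * (f + (size_t)nf * j)],
               n, L, c, pad, false);
    }
    const double* __restrict xj = &X(0, j * L);
    double gb = 0.0;
    for (size_t s = 0; s < nl; ++s) {
      const double r = 1.0 / (1.0 + std::exp(-P[s]));
      double rc = r < eps ? eps : (r > 1.0 - eps ? 1.0 - eps : r);
      loss -= xj[s] * std::log(rc) + (1.0 - xj[s]) * std::log(1.0 - rc);
      const double d = (r - xj[s]) * invN;
      dP[s] = d;
      gb += d;
    }
    gbd[j] = gb;
    for (int f = 0; f < nf; ++f) {
      conv_kgrad(Z[f].data(), dP.data(), &gkd[(size_t)c * (f + (size_t)nf * j)],
                 n, L, c, pad);
      conv_add(dP.data(), dZ[f].data(), &kd[(size_t)c * (f + (size_t)nf * j)],
               n, L, c, pad, true);
    }
  }

  std::vector<double> dY(nl, 0.0);
  for (int f = 0; f < nf; ++f) {
    double gb = 0.0;
    for (size_t s = 0; s < nl; ++s) {
      const double g = Zpre[f][s] > 0.0 ? dZ[f][s] : 0.0;
      dZ[f][s] = g;
      gb += g;
    }
    gb2[f] = gb;
    conv_kgrad(Y.data(), dZ[f].data(), &gk2[(size_t)c * f], n, L, c, pad);
    conv_add(dZ[f].data(), dY.data(), &k2(0, f), n, L, c, pad, true);
  }
  for (int ch = 0; ch < C; ++ch) {
    const double* __restrict xc = &X(0, ch * L);
    double acc = 0.0;
    for (size_t s = 0; s < nl; ++s) acc += xc[s] * dY[s];
    gw1[ch] = acc;
    // gb1 accumulates once below
  }
  for (size_t s = 0; s < nl; ++s) gb1 += dY[s];

  gk2.attr("dim") = Dimension(c, nf);
  gkd.attr("dim") = Dimension(c, nf, C);
  return List::create(_["loss"] = loss * invN, _["w1"] = gw1, _["b1"] = gb1,
                      _["k2"] = gk2, _["b2"] = gb2, _["kd"] = gkd, _["bd"] = gbd);
}
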