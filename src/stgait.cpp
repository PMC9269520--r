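// Compiled input batch-normalization kernels.
//
// Feature maps are dense column-major (C, T, N, V) arrays. These kernels
// mirror the pure-R reference implementation of the input batch
// normalization in R/engine.R, against which they are tested; the rest of
// the network's compiled path lives in netbatch.cpp.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---- batch normalization over the (channel, joint) axis ----

// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector X, IntegerVector d, NumericMatrix gamma,
                NumericMatrix beta, NumericMatrix rmean, NumericMatrix rvar,
                bool train, double eps) {
  const int C = d[0], T = d[1], N = d[2], V = d[3];
  const double nred = (double)T * N;
  NumericMatrix m(C, V), var(C, V);
  if (train) {
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n)
        for (int t = 0; t < T; ++t) {
          const double* xp = &X[(size_t)C * (t + (size_t)T * (n + (size_t)N * v))];
          for (int c = 0; c < C; ++c) {
            m(c, v) += xp[c];
            var(c, v) += xp[c] * xp[c];
          }
        }
    for (int v = 0; v < V; ++v)
      for (int c = 0; c < C; ++c) {
        m(c, v) /= nred;
        double vv = var(c, v) / nred - m(c, v) * m(c, v);
        var(c, v) = vv > 0 ? vv : 0;
      }
  } else {
    for (int v = 0; v < V; ++v)
      for (int c = 0; c < C; ++c) {
        m(c, v) = rmean(c, v);
        var(c, v) = rvar(c, v);
      }
  }
  NumericMatrix istd(C, V);
  for (int v = 0; v < V; ++v)
    for (int c = 0; c < C; ++c) istd(c, v) = 1.0 / std::sqrt(var(c, v) + eps);
  NumericVector xhat(X.size()), out(X.size());
  for (int v = 0; v < V; ++v)
    for (int n = 0; n < N; ++n)
      for (int t = 0; t < T; ++t) {
        size_t base = (size_t)C * (t + (size_t)T * (n + (size_t)N * v));
        for (int c = 0; c < C; ++c) {
          double xh = (X[base + c] - m(c, v)) * istd(c, v);
          xhat[base + c] = xh;
          out[base + c] = gamma(c, v) * xh + beta(c, v);
        }
      }
  out.attr("dim") = d;
  xhat.attr("dim") = d;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd,
                      _["bmean"] = m, _["bvar"] = var);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector dY, NumericVector xhat, IntegerVector d,
                NumericMatrix gamma, NumericMatrix istd, bool train) {
  const int C = d[0], T = d[1], N = d[2], V = d[3];
  const double nred = (double)T * N;
  NumericMatrix dgamma(C, V), dbeta(C, V), mh(C, V), mx(C, V);
  for (int v = 0; v < V; ++v)
    for (int n = 0; n < N; ++n)
      for (int t = 0; t < T; ++t) {
        size_t base = (size_t)C * (t + (size_t)T * (n + (size_t)N * v));
        for (int c = 0; c < C; ++c) {
          double dxh = dY[base + c] * gamma(c, v);
          dgamma(c, v) += dY[base + c] * xhat[base + c];
          dbeta(c, v) += dY[base + c];
          mh(c, v) += dxh;
          mx(c, v) += dxh * xhat[base + c];
        }
      }
  NumericVector dX(dY.size());
  for (int v = 0; v < V; ++v)
    for (int n = 0; n < N; ++n)
      for (int t = 0; t < T; ++t) {
        size_t base = (size_t)C * (t + (size_t)T * (n + (size_t)N * v));
        for (int c = 0; c < C; ++c) {
          double dxh = dY[base + c] * gamma(c, v);
          if (train) {
            dX[base + c] = (dxh - mh(c, v) / nred -
                            xhat[base + c] * mx(c, v) / nred) * istd(c, v);
          } else {
            dX[base + c] = dxh * istd(c, v);
          }
        }
      }
  dX.attr("dim") = d;
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
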