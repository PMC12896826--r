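// Hot inner kernels of the 1-D CNN: kernel-3 column unfolding and its
// transpose, and fused bias + batch-norm + ReLU passes. Activations are
// (channels x length*batch) matrices, sequence position fastest. The
// backward pass recomputes the normalized activations from the cached
// pre-normalization conv output instead of storing them.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& M, int L, int N) {
  const int C = M.nrow();
  NumericMatrix col(3 * C, L * N);
  for (int n = 0; n < N; ++n)
    for (int l = 0; l < L; ++l) {
      const int j = n * L + l;
      for (int o = 0; o < 3; ++o) {
        const int ls = l + o - 1;
        if (ls < 0 || ls >= L) continue;
        const int js = n * L + ls;
        std::copy(&M(0, js), &M(0, js) + C, &col(o * C, j));
      }
    }
  return col;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& dcol, int C, int L, int N) {
  NumericMatrix dA(C, L * N);
  for (int n = 0; n < N; ++n)
    for (int l = 0; l < L; ++l) {
      const int j = n * L + l;
      for (int o = 0; o < 3; ++o) {
        const int ld = l + o - 1;
        if (ld < 0 || ld >= L) continue;
        double* dst = &dA(0, n * L + ld);
        const double* src = &dcol(o * C, j);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  return dA;
}

// per-channel mean and population variance of Z + bias
// [[Rcpp::export]]
List cpp_row_moments_bias(const NumericMatrix& Z, const NumericVector& b) {
  const int C = Z.nrow(), m = Z.ncol();
  NumericVector mu(C), v(C);
  for (int j = 0; j < m; ++j) {
    const double* z = &Z(0, j);
    for (int c = 0; c < C; ++c) {
      const double x = z[c] + b[c];
      mu[c] += x; v[c] += x * x;
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    v[c] = std::max(v[c] / m - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mu"] = mu, _["v"] = v);
}

// out = gamma * ((Z + b - mu) * invstd) + beta, optionally ReLU-clipped
// [[Rcpp::export]]
NumericMatrix cpp_bn_fwd(const NumericMatrix& Z, const NumericVector& b,
                         const NumericVector& gamma, const NumericVector& beta,
                         const NumericVector& mu, const NumericVector& invstd,
                         bool relu) {
  const int C = Z.nrow(), m = Z.ncol();
  NumericMatrix Y(C, m);
  for (int j = 0; j < m; ++j) {
    const double* z = &Z(0, j);
    double* y = &Y(0, j);
    for (int c = 0; c < C; ++c) {
      double out = gamma[c] * ((z[c] + b[c] - mu[c]) * invstd[c]) + beta[c];
      y[c] = (relu && out < 0) ? 0.0 : out;
    }
  }
  return Y;
}

// batch-statistics BN backward; xhat recomputed from cached conv output
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericMatrix& Z,
                const NumericVector& b, const NumericVector& mu,
                const NumericVector& invstd, const NumericVector& gamma) {
  const int C = dY.nrow(), m = dY.ncol();
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (int j = 0; j < m; ++j) {
    const double* dy = &dY(0, j);
    const double* z = &Z(0, j);
    for (int c = 0; c < C; ++c) {
      const double xh = (z[c] + b[c] - mu[c]) * invstd[c];
      const double dx = dy[c] * gamma[c];
      dgamma[c] += dy[c] * xh;
      dbeta[c] += dy[c];
      s1[c] += dx;
      s2[c] += dx * xh;
    }
  }
  NumericMatrix dZ(C, m);
  for (int j = 0; j < m; ++j) {
    const double* dy = &dY(0, j);
    const double* z = &Z(0, j);
    double* dz = &dZ(0, j);
    for (int c = 0; c < C; ++c) {
      const double xh = (z[c] + b[c] - mu[c]) * invstd[c];
      const double dx = dy[c] * gamma[c];
      dz[c] = invstd[c] / m * (m * dx - s1[c] - xh * s2[c]);
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// out-of-place ReLU mask product: dX = dY * (act > 0)
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& dY, const NumericMatrix& act) {
  const int C = dY.nrow(), m = dY.ncol();
  NumericMatrix dX(C, m);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, j) = act(c, j) > 0 ? dY(c, j) : 0.0;
  return dX;
}

// ReLU(A + B), the residual merge
// [[Rcpp::export]]
NumericMatrix cpp_add_relu(const NumericMatrix& A, const NumericMatrix& B) {
  const int C = A.nrow(), m = A.ncol();
  NumericMatrix Y(C, m);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c) {
      const double s = A(c, j) + B(c, j);
      Y(c, j) = s > 0 ? s : 0.0;
    }
  return Y;
}
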