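// Compute kernels for the spatial/temporal transformer.
//
// Grouped multi-head scaled dot-product attention: tokens are stored as a
// (G * Tk) x D matrix with the Tk tokens of each of the G groups in
// contiguous rows; heads are contiguous column slices of width dk = D / H.
// Attention is computed independently per (group, head):
//   A = softmax(Q K^T / sqrt(dk)) row-wise, out = A V.
// Q, K and V arrive fused as one (G * Tk) x 3D matrix (column blocks
// Q | K | V). Token counts per group are small (channels or frames), so the
// per-group work uses plain loops rather than BLAS calls.
//
// Also here: row-wise layer normalization and exact GELU (x * Phi(x)),
// forward and backward, and a fused bias add.

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// [[Rcpp::export]]
List mha_qkv_forward_cpp(const arma::mat& QKV, int G, int Tk, int H) {
  const int n = QKV.n_rows;
  const int D = QKV.n_cols / 3;
  if (D % H != 0) stop("embedding width not divisible by number of heads");
  if (n != G * Tk) stop("token rows do not match G * Tk");
  const int dk = D / H;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dk));
  mat out(n, D);
  cube attn(Tk, Tk, static_cast<size_t>(G) * H);
  const double* q = QKV.memptr();
  const double* k = q + static_cast<size_t>(n) * D;
  const double* v = k + static_cast<size_t>(n) * D;
  double* o = out.memptr();
  std::vector<double> S(Tk * Tk);
  for (int g = 0; g < G; ++g) {
    const int r0 = g * Tk;
    for (int h = 0; h < H; ++h) {
      const size_t c0 = static_cast<size_t>(h) * dk;
      // scores
      for (int i = 0; i < Tk; ++i) {
        for (int j = 0; j < Tk; ++j) {
          double s = 0.0;
          for (int d = 0; d < dk; ++d) {
            s += q[r0 + i + (c0 + d) * n] * k[r0 + j + (c0 + d) * n];
          }
          S[i + j * Tk] = s * scale;
        }
      }
      // row-wise softmax
      double* A = attn.slice_memptr(static_cast<size_t>(g) * H + h);
      for (int i = 0; i < Tk; ++i) {
        double m = S[i];
        for (int j = 1; j < Tk; ++j) m = std::max(m, S[i + j * Tk]);
        double z = 0.0;
        for (int j = 0; j < Tk; ++j) {
          double e = std::exp(S[i + j * Tk] - m);
          A[i + j * Tk] = e;
          z += e;
        }
        const double inv = 1.0 / z;
        for (int j = 0; j < Tk; ++j) A[i + j * Tk] *= inv;
      }
      // out = A * V
      for (int d = 0; d < dk; ++d) {
        const size_t col = (c0 + d) * n;
        for (int i = 0; i < Tk; ++i) {
          double s = 0.0;
          for (int j = 0; j < Tk; ++j) s += A[i + j * Tk] * v[r0 + j + col];
          o[r0 + i + col] = s;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["attn"] = attn);
}

// [[Rcpp::export]]
arma::mat mha_qkv_backward_cpp(const arma::mat& dOut, const arma::mat& QKV,
                               const arma::cube& attn, int G, int Tk, int H) {
  const int n = QKV.n_rows;
  const int D = QKV.n_cols / 3;
  const int dk = D / H;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dk));
  mat dQKV(n, 3 * D, fill::zeros);
  const double* q = QKV.memptr();
  const double* k = q + static_cast<size_t>(n) * D;
  const double* v = k + static_cast<size_t>(n) * D;
  double* dq = dQKV.memptr();
  double* dkp = dq + static_cast<size_t>(n) * D;
  double* dv = dkp + static_cast<size_t>(n) * D;
  const double* dO = dOut.memptr();
  std::vector<double> dA(Tk * Tk), dS(Tk * Tk);
  for (int g = 0; g < G; ++g) {
    const int r0 = g * Tk;
    for (int h = 0; h < H; ++h) {
      const size_t c0 = static_cast<size_t>(h) * dk;
      const double* A = attn.slice_memptr(static_cast<size_t>(g) * H + h);
      // dA = dOut V^T ; dV = A^T dOut
      for (int i = 0; i < Tk; ++i) {
        for (int j = 0; j < Tk; ++j) dA[i + j * Tk] = 0.0;
      }
      for (int d = 0; d < dk; ++d) {
        const size_t col = (c0 + d) * n;
        for (int i = 0; i < Tk; ++i) {
          const double doid = dO[r0 + i + col];
          for (int j = 0; j < Tk; ++j) {
            dA[i + j * Tk] += doid * v[r0 + j + col];
            dv[r0 + j + col] += A[i + j * Tk] * doid;
          }
        }
      }
      // softmax backward per query row
      for (int i = 0; i < Tk; ++i) {
        double rs = 0.0;
        for (int j = 0; j < Tk; ++j) rs += dA[i + j * Tk] * A[i + j * Tk];
        for (int j = 0; j < Tk; ++j) {
          dS[i + j * Tk] = A[i + j * Tk] * (dA[i + j * Tk] - rs) * scale;
        }
      }
      // dQ = dS K ; dK = dS^T Q
      for (int d = 0; d < dk; ++d) {
        const size_t col = (c0 + d) * n;
        for (int i = 0; i < Tk; ++i) {
          double s = 0.0;
          for (int j = 0; j < Tk; ++j) {
            const double ds = dS[i + j * Tk];
            s += ds * k[r0 + j + col];
            dkp[r0 + j + col] += ds * q[r0 + i + col];
          }
          dq[r0 + i + col] = s;
        }
      }
    }
  }
  return dQKV;
}

// [[Rcpp::export]]
List ln_forward_cpp(const arma::mat& X, const arma::vec& gamma,
                    const arma::vec& beta, double eps = 1e-5) {
  const int n = X.n_rows, D = X.n_cols;
  mat out(n, D), xhat(n, D);
  vec inv(n);
  const double* x = X.memptr();
  double* o = out.memptr();
  double* xh = xhat.memptr();
  for (int r = 0; r < n; ++r) {
    double mu = 0.0;
    for (int c = 0; c < D; ++c) mu += x[r + static_cast<size_t>(c) * n];
    mu /= D;
    double vv = 0.0;
    for (int c = 0; c < D; ++c) {
      const double d = x[r + static_cast<size_t>(c) * n] - mu;
      vv += d * d;
    }
    const double iv = 1.0 / std::sqrt(vv / D + eps);
    inv[r] = iv;
    for (int c = 0; c < D; ++c) {
      const size_t idx = r + static_cast<size_t>(c) * n;
      const double z = (x[idx] - mu) * iv;
      xh[idx] = z;
      o[idx] = z * gamma[c] + beta[c];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List ln_backward_cpp(const arma::mat& dY, const arma::mat& xhat,
                     const arma::vec& inv, const arma::vec& gamma) {
  const int n = dY.n_rows, D = dY.n_cols;
  mat dX(n, D);
  vec dgamma(D, fill::zeros), dbeta(D, fill::zeros);
  const double* dy = dY.memptr();
  const double* xh = xhat.memptr();
  double* dx = dX.memptr();
  for (int r = 0; r < n; ++r) {
    double m1 = 0.0, m2 = 0.0;
    for (int c = 0; c < D; ++c) {
      const size_t idx = r + static_cast<size_t>(c) * n;
      const double dxh = dy[idx] * gamma[c];
      m1 += dxh;
      m2 += dxh * xh[idx];
    }
    m1 /= D; m2 /= D;
    const double iv = inv[r];
    for (int c = 0; c < D; ++c) {
      const size_t idx = r + static_cast<size_t>(c) * n;
      const double dxh = dy[idx] * gamma[c];
      dx[idx] = (dxh - m1 - xh[idx] * m2) * iv;
      dgamma[c] += dy[idx] * xh[idx];
      dbeta[c] += dy[idx];
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// [[Rcpp::export]]
List gelu_forward_cpp(const arma::mat& X) {
  mat out(size(X)), pn(size(X));
  const double* x = X.memptr();
  double* o = out.memptr();
  double* p = pn.memptr();
  const size_t m = X.n_elem;
  for (size_t i = 0; i < m; ++i) {
    p[i] = phi_cdf(x[i]);
    o[i] = x[i] * p[i];
  }
  return List::create(_["out"] = out, _["pn"] = pn);
}

// [[Rcpp::export]]
arma::mat gelu_backward_cpp(const arma::mat& dY, const arma::mat& X,
                            const arma::mat& pn) {
  mat dX(size(X));
  const double* dy = dY.memptr();
  const double* x = X.memptr();
  const double* p = pn.memptr();
  double* dx = dX.memptr();
  const size_t m = X.n_elem;
  const double c = 0.3989422804014327;  // 1 / sqrt(2 pi)
  for (size_t i = 0; i < m; ++i) {
    dx[i] = dy[i] * (p[i] + x[i] * c * std::exp(-0.5 * x[i] * x[i]));
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat add_bias_cpp(const arma::mat& M, const arma::vec& b) {
  mat out(size(M));
  const int n = M.n_rows, D = M.n_cols;
  const double* m = M.memptr();
  double* o = out.memptr();
  for (int c = 0; c < D; ++c) {
    const double bc = b[c];
    const size_t off = static_cast<size_t>(c) * n;
    for (int r = 0; r < n; ++r) o[off + r] = m[off + r] + bc;
  }
  return out;
}
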