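// Deterministic CNN layer kernels for the descriptor network: 3x3
// same-padding convolution (batch-wide im2col + one GEMM), 2x2 max
// pooling, and the tanh-approximation GELU, each with its backward pass.
// Batches are cubes with slices laid out sample-major, channel-minor:
// slice index n * C + c. Single-threaded BLAS calls on fixed operand
// order keep results bit-reproducible run to run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// batch-wide im2col: rows = N*H*W output positions, cols = C*9
static void im2col3_batch(const cube& x, uword C, mat& out) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword N = x.n_slices / C;
  const uword HW = H * W;
  uword col = 0;
  for (uword c = 0; c < C; ++c) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++col) {
        double* o = out.colptr(col);
        for (uword n = 0; n < N; ++n) {
          const mat& ch = x.slice(n * C + c);
          double* on = o + n * HW;
          for (uword j = 0; j < W; ++j) {
            int sj = (int)j + dx;
            double* oj = on + j * H;
            if (sj < 0 || sj >= (int)W) {
              std::fill(oj, oj + H, 0.0);
              continue;
            }
            const double* src = ch.colptr(sj);
            if (dy == 0) {
              std::copy(src, src + H, oj);
            } else if (dy < 0) {
              oj[0] = 0.0;
              std::copy(src, src + H - 1, oj + 1);
            } else {
              std::copy(src + 1, src + H, oj);
              oj[H - 1] = 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_forward")]]
arma::cube conv_forward(const arma::cube& x, int C,
                        const arma::mat& Wt, const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword N = x.n_slices / (uword)C;
  const uword K = Wt.n_cols;
  const uword HW = H * W;
  mat cols(N * HW, (uword)C * 9);
  im2col3_batch(x, (uword)C, cols);
  mat z = cols * Wt;                 // (N*H*W) x K
  z.each_row() += b.t();
  cube y(H, W, N * K);
  for (uword n = 0; n < N; ++n)
    for (uword k = 0; k < K; ++k)
      std::copy(z.colptr(k) + n * HW, z.colptr(k) + (n + 1) * HW,
                y.slice(n * K + k).memptr());
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_backward")]]
Rcpp::List conv_backward(const arma::cube& x, int C, const arma::mat& Wt,
                         const arma::cube& dy, bool needDx) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword N = x.n_slices / (uword)C;
  const uword K = Wt.n_cols;
  const uword HW = H * W;
  mat cols(N * HW, (uword)C * 9);
  im2col3_batch(x, (uword)C, cols);
  mat dz(N * HW, K);
  for (uword n = 0; n < N; ++n)
    for (uword k = 0; k < K; ++k)
      std::copy(dy.slice(n * K + k).memptr(),
                dy.slice(n * K + k).memptr() + HW,
                dz.colptr(k) + n * HW);
  mat dW = cols.t() * dz;
  vec db = sum(dz, 0).t();
  cube dx(H, W, needDx ? x.n_slices : 1, fill::zeros);
  if (needDx) {
    mat dcols = dz * Wt.t();         // (N*H*W) x (C*9)
    uword col = 0;
    for (uword c = 0; c < C; ++c) {
      for (int dyy = -1; dyy <= 1; ++dyy) {
        for (int dxx = -1; dxx <= 1; ++dxx, ++col) {
          const double* dcp = dcols.colptr(col);
          for (uword n = 0; n < N; ++n) {
            mat& dch = dx.slice(n * C + c);
            const double* dn = dcp + n * HW;
            for (uword j = 0; j < W; ++j) {
              int sj = (int)j + dxx;
              if (sj < 0 || sj >= (int)W) continue;
              double* dst = dch.colptr(sj);
              const double* sj_col = dn + j * H;
              if (dyy == 0) {
                for (uword i = 0; i < H; ++i) dst[i] += sj_col[i];
              } else if (dyy < 0) {
                for (uword i = 1; i < H; ++i) dst[i - 1] += sj_col[i];
              } else {
                for (uword i = 0; i + 1 < H; ++i) dst[i + 1] += sj_col[i];
              }
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; records argmax for the backward pass
// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
Rcpp::List maxpool_forward(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, S);
  ucube idx(Ho, Wo, S);
  for (uword s = 0; s < S; ++s) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        uword bi = 2 * i, bj = 2 * j, best = 0;
        double v = x(bi, bj, s), cand;
        cand = x(bi + 1, bj, s); if (cand > v) { v = cand; best = 1; }
        cand = x(bi, bj + 1, s); if (cand > v) { v = cand; best = 2; }
        cand = x(bi + 1, bj + 1, s); if (cand > v) { v = cand; best = 3; }
        y(i, j, s) = v;
        idx(i, j, s) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
arma::cube maxpool_backward(const arma::ucube& idx, const arma::cube& dy,
                            int H, int W) {
  const uword Ho = dy.n_rows, Wo = dy.n_cols, S = dy.n_slices;
  cube dx((uword)H, (uword)W, S, fill::zeros);
  for (uword s = 0; s < S; ++s)
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i) {
        uword b = idx(i, j, s);
        dx(2 * i + (b & 1u), 2 * j + (b >> 1), s) = dy(i, j, s);
      }
  return dx;
}

static const double kGeluC = 0.7978845608028654; // sqrt(2/pi)

// GELU, tanh approximation
// [[Rcpp::export(name = ".cpp_gelu_forward")]]
arma::cube gelu_forward(const arma::cube& x) {
  cube y = x;
  y.transform([](double v) {
    double t = std::tanh(kGeluC * (v + 0.044715 * v * v * v));
    return 0.5 * v * (1.0 + t);
  });
  return y;
}

// [[Rcpp::export(name = ".cpp_gelu_backward")]]
arma::cube gelu_backward(const arma::cube& x, const arma::cube& dy) {
  cube dx = x;
  for (uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    double u = kGeluC * (v + 0.044715 * v * v * v);
    double t = std::tanh(u);
    double du = kGeluC * (1.0 + 3.0 * 0.044715 * v * v);
    double g = 0.5 * (1.0 + t) + 0.5 * v * (1.0 - t * t) * du;
    dx(i) = g * dy(i);
  }
  return dx;
}
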