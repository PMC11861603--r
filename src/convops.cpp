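// Convolution / pooling kernels for the fusion CNN.
// Batch tensors are R arrays in column-major order with dims (H, W, C, N).
// Convolutions are stride-1 with "same" zero padding (odd kernels only);
// arithmetic is single precision (im2col + sgemm via Armadillo/BLAS).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Build the im2col matrix K (kh*kw*C rows, H*W*N cols) from x.
static arma::fmat im2col(const double* x, int H, int W, int C, int N,
                         int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const long HW = (long)H * W;
  arma::fmat K((arma::uword)(kh * kw * C), (arma::uword)(HW * N));
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * (dj + kw * c);
        for (int n = 0; n < N; ++n) {
          const double* xp = x + H * (long)W * (c + (long)C * n);
          float* Kr = K.memptr() + r; // row r, stride = n_rows
          const arma::uword nr = K.n_rows;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj - pw;
            long colbase = (long)(j)*H + HW * n;
            if (js < 0 || js >= W) {
              for (int i = 0; i < H; ++i) Kr[(colbase + i) * nr] = 0.0f;
            } else {
              const double* col = xp + (long)js * H;
              for (int i = 0; i < H; ++i) {
                const int is = i + di - ph;
                Kr[(colbase + i) * nr] =
                    (is < 0 || is >= H) ? 0.0f : (float)col[is];
              }
            }
          }
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         int kh, int kw) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int Cout = w.nrow();
  if (w.ncol() != kh * kw * C) stop("weight shape mismatch");
  arma::fmat K = im2col(REAL(x), H, W, C, N, kh, kw);
  arma::fmat Wm(Cout, w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < Cout; ++i) Wm(i, j) = (float)w(i, j);
  arma::fmat out = Wm * K; // Cout x (H*W*N)
  const long HW = (long)H * W;
  NumericVector res(HW * Cout * (long)N);
  res.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* rp = REAL(res);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float bb = (float)b[co];
      double* dst = rp + HW * (co + (long)Cout * n);
      for (long p = 0; p < HW; ++p) dst[p] = out(co, p + HW * n) + bb;
    }
  return res;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                int kh, int kw) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  int H2, W2, Cout, N2;
  dims4(dout, H2, W2, Cout, N2);
  if (H2 != H || W2 != W || N2 != N || Cout != w.nrow())
    stop("gradient shape mismatch");
  const long HW = (long)H * W;
  arma::fmat K = im2col(REAL(x), H, W, C, N, kh, kw);
  // gather dout into (Cout x HW*N)
  arma::fmat dO(Cout, (arma::uword)(HW * N));
  const double* dp = REAL(dout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dp + HW * (co + (long)Cout * n);
      for (long p = 0; p < HW; ++p) dO(co, p + HW * n) = (float)src[p];
    }
  arma::fmat Wm(Cout, w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < Cout; ++i) Wm(i, j) = (float)w(i, j);

  arma::fmat dW = dO * K.t();            // Cout x (kh*kw*C)
  arma::fvec db = arma::sum(dO, 1);      // Cout
  arma::fmat dK = Wm.t() * dO;           // (kh*kw*C) x (HW*N)

  // col2im scatter-add
  NumericVector dx(HW * C * (long)N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* dxp = REAL(dx);
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * (dj + kw * c);
        const float* Kr = dK.memptr() + r;
        const arma::uword nr = dK.n_rows;
        for (int n = 0; n < N; ++n) {
          double* xp = dxp + H * (long)W * (c + (long)C * n);
          for (int j = 0; j < W; ++j) {
            const int js = j + dj - pw;
            if (js < 0 || js >= W) continue;
            long colbase = (long)j * H + HW * n;
            double* col = xp + (long)js * H;
            for (int i = 0; i < H; ++i) {
              const int is = i + di - ph;
              if (is >= 0 && is < H) col[is] += Kr[(colbase + i) * nr];
            }
          }
        }
      }

  NumericMatrix dWr(Cout, w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < Cout; ++i) dWr(i, j) = dW(i, j);
  NumericVector dbr(Cout);
  for (int i = 0; i < Cout; ++i) dbr[i] = db(i);
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int ph, int pw) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (H % ph != 0 || W % pw != 0) stop("input not divisible by pool size");
  const int Ho = H / ph, Wo = W / pw;
  const long HWo = (long)Ho * Wo;
  NumericVector out(HWo * C * (long)N);
  IntegerVector idx(HWo * C * (long)N); // 1-based linear index into x
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long xoff = (long)H * W * (c + (long)C * n);
      const long ooff = HWo * (c + (long)C * n);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double best = -1e300;
          long bi = -1;
          for (int dj = 0; dj < pw; ++dj)
            for (int di = 0; di < ph; ++di) {
              const long li = xoff + (long)(jo * pw + dj) * H + io * ph + di;
              if (xp[li] > best) { best = xp[li]; bi = li; }
            }
          const long lo = ooff + (long)jo * Ho + io;
          op[lo] = best;
          ip[lo] = (int)(bi + 1);
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector idx,
                          IntegerVector xdim) {
  long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = REAL(dx);
  const double* dp = REAL(dout);
  const int* ip = INTEGER(idx);
  const long m = dout.size();
  for (long k = 0; k < m; ++k) dxp[ip[k] - 1] += dp[k];
  return dx;
}

// In-place Adam update of a parameter array and its moment buffers.
// The caller owns all four arrays exclusively (layer environments).
// [[Rcpp::export(name = ".adam_update")]]
void adam_update(NumericVector w, NumericVector m, NumericVector v,
                 NumericVector g, double lr, double beta1, double beta2,
                 double eps, double corr1, double corr2) {
  const R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam buffers must match the parameter size");
  double* wp = REAL(w); double* mp = REAL(m);
  double* vp = REAL(v); const double* gp = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / corr1) / (std::sqrt(vp[i] / corr2) + eps);
  }
}

// ReLU forward in place; returns nothing (mask recomputed in backward).
// [[Rcpp::export(name = ".relu_fwd_inplace")]]
void relu_fwd_inplace(NumericVector x) {
  double* xp = REAL(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (xp[i] < 0) xp[i] = 0;
}

// ReLU backward: zero gradient where the (post-activation) output was 0.
// [[Rcpp::export(name = ".relu_bwd_inplace")]]
void relu_bwd_inplace(NumericVector dout, NumericVector out) {
  double* dp = REAL(dout);
  const double* op = REAL(out);
  const R_xlen_t n = dout.size();
  if (out.size() != n) stop("shape mismatch");
  for (R_xlen_t i = 0; i < n; ++i) if (op[i] <= 0) dp[i] = 0;
}
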