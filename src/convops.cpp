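// Low-level tensor kernels for the CPU training engine.
// Tensor layout everywhere: column-major R arrays dim (H, W, C, N).
// Convolutions are "same"-padded (zero padding); even kernels pad
// bottom/right-heavy; dilation spaces the kernel taps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int pad_before(int k, int r) { return ((k - 1) * r) / 2; }

// im2col for one image: output (H*W) x (kh*kw*Cin)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int r, arma::mat& out) {
  const int pb_h = pad_before(kh, r), pb_w = pad_before(kw, r);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* dst = out.colptr(col);
        const int oh = ki * r - pb_h, ow = kj * r - pb_w;
        for (int w = 0; w < W; ++w) {
          const int iw = w + ow;
          if (iw < 0 || iw >= W) {
            for (int h = 0; h < H; ++h) dst[h + H * w] = 0.0;
          } else {
            const double* src = x + H * (iw + W * c);
            for (int h = 0; h < H; ++h) {
              const int ih = h + oh;
              dst[h + H * w] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
            }
          }
        }
      }
    }
  }
}

// scatter-add of columns back to the padded image (adjoint of im2col)
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int r, double* gx) {
  const int pb_h = pad_before(kh, r), pb_w = pad_before(kw, r);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* src = cols.colptr(col);
        const int oh = ki * r - pb_h, ow = kj * r - pb_w;
        for (int w = 0; w < W; ++w) {
          const int iw = w + ow;
          if (iw < 0 || iw >= W) continue;
          double* dst = gx + H * (iw + W * c);
          for (int h = 0; h < H; ++h) {
            const int ih = h + oh;
            if (ih >= 0 && ih < H) dst[ih] += src[h + H * w];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fw")]]
NumericVector conv_fw(NumericVector x, NumericVector w, NumericVector b,
                      int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv_fw: channel mismatch (%d vs %d)", Cin, C);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat cols(H * W, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, dilation, cols);
    arma::mat out(y.begin() + static_cast<R_xlen_t>(n) * H * W * Cout,
                  H * W, Cout, false, true);
    out = cols * Wm;
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bw")]]
List conv_bw(NumericVector x, NumericVector w, NumericVector gy,
             int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Gw(gw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat cols(H * W, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, dilation, cols);
    arma::mat G(const_cast<double*>(gy.begin()) +
                static_cast<R_xlen_t>(n) * H * W * Cout,
                H * W, Cout, false);
    Gw += cols.t() * G;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(G.col(co));
    arma::mat gcols = G * Wm.t();
    col2im(gcols, H, W, C, kh, kw, dilation,
           gx.begin() + static_cast<R_xlen_t>(n) * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = static_cast<R_xlen_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++o) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              const R_xlen_t i = base +
                (2 * h + dh) + static_cast<R_xlen_t>(H) * ((2 * w + dw) + W * c);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          }
          y[o] = best; idx[o] = static_cast<int>(bi);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector gy,
                         IntegerVector xdim) {
  R_xlen_t n = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export(name = ".upsample_fw")]]
NumericVector upsample_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(static_cast<R_xlen_t>(4) * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  R_xlen_t i = 0;
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* src = x.begin() + cn * H * W;
    double* dst = y.begin() + cn * 4 * H * W;
    for (int w = 0; w < 2 * W; ++w) {
      for (int h = 0; h < 2 * H; ++h) {
        dst[h + 2 * H * w] = src[(h / 2) + H * (w / 2)];
      }
    }
  }
  (void)i;
  return y;
}

// [[Rcpp::export(name = ".upsample_bw")]]
NumericVector upsample_bw(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* src = gy.begin() + cn * H2 * W2;
    double* dst = gx.begin() + cn * H * W;
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        dst[(h / 2) + H * (w / 2)] += src[h + H2 * w];
      }
    }
  }
  return gx;
}
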