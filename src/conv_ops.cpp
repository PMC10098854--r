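// Convolution primitives for the cGAN engine.
//
// Layout conventions (match R's column-major arrays):
//   feature map  : arma::cube (H, W, C)  ==  R array dim c(H, W, C)
//   conv weights : matrix (k*k*Cin, Cout), i.e. R array dim c(k, k, Cin, Cout)
//                  flattened; patch element order is (row offset, col offset,
//                  channel), column-major.
//
// "same" padding geometry (outH/outW, pad offsets) is computed on the R side
// and passed in, so a single set of primitives serves strided convolution,
// its data/weight gradients, and (by role reversal) transposed convolution.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col(const cube& x, const int k, const int stride,
                  const int pad_t, const int pad_l,
                  const int outH, const int outW) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat P(outH * (sword)outW, k * (sword)k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int col = a + k * b + k * k * c;
        for (int ow = 0; ow < outW; ++ow) {
          const int iw = ow * stride - pad_l + b;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            const int ih = oh * stride - pad_t + a;
            if (ih < 0 || ih >= H) continue;
            P(oh + outH * (sword)ow, col) = x(ih, iw, c);
          }
        }
      }
    }
  }
  return P;
}

// scatter-add of patch-matrix gradients back onto the input grid
static cube col2im(const mat& P, const int k, const int stride,
                   const int pad_t, const int pad_l,
                   const int outH, const int outW,
                   const int H, const int W, const int C) {
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int col = a + k * b + k * k * c;
        for (int ow = 0; ow < outW; ++ow) {
          const int iw = ow * stride - pad_l + b;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            const int ih = oh * stride - pad_t + a;
            if (ih < 0 || ih >= H) continue;
            gx(ih, iw, c) += P(oh + outH * (sword)ow, col);
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& K,
                        const int k, const int stride,
                        const int pad_t, const int pad_l,
                        const int outH, const int outW) {
  const mat P = im2col(x, k, stride, pad_t, pad_l, outH, outW);
  const mat Y = P * K;  // (outH*outW) x Cout
  cube out(outH, outW, K.n_cols);
  for (uword c = 0; c < K.n_cols; ++c)
    out.slice(c) = reshape(Y.col(c), outH, outW);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv_bwd_data(const arma::cube& gy, const arma::mat& K,
                             const int k, const int stride,
                             const int pad_t, const int pad_l,
                             const int H, const int W) {
  const int outH = gy.n_rows, outW = gy.n_cols;
  mat Gy(outH * (sword)outW, gy.n_slices);
  for (uword c = 0; c < gy.n_slices; ++c)
    Gy.col(c) = vectorise(gy.slice(c));
  const mat Pg = Gy * K.t();  // (outH*outW) x (k*k*Cin)
  const int C = K.n_rows / (k * k);
  return col2im(Pg, k, stride, pad_t, pad_l, outH, outW, H, W, C);
}

// [[Rcpp::export]]
arma::mat cpp_conv_bwd_weight(const arma::cube& x, const arma::cube& gy,
                              const int k, const int stride,
                              const int pad_t, const int pad_l) {
  const int outH = gy.n_rows, outW = gy.n_cols;
  const mat P = im2col(x, k, stride, pad_t, pad_l, outH, outW);
  mat Gy(outH * (sword)outW, gy.n_slices);
  for (uword c = 0; c < gy.n_slices; ++c)
    Gy.col(c) = vectorise(gy.slice(c));
  return P.t() * Gy;  // (k*k*Cin) x Cout
}
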