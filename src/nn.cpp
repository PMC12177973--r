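// Convolution primitives for the encoder-decoder segmentation networks.
// Data layout matches R arrays dim c(H, W, C): arma::cube with
// rows = H, cols = W, slices = C (column-major throughout).
//
// Convolution weights are matrices (OC x IC*kh*kw); the column index of a
// weight matrix is ((c*kh + ki)*kw + kj) for input channel c and kernel
// offset (ki, kj) in (row, col) order. Transposed-convolution weights are
// (IC x OC*kh*kw) with the same inner ordering over output channels.
//
// Patch matrices are kept position-major -- (oh*ow) x (C*kh*kw) -- so the
// innermost gather/scatter loops walk contiguous memory; the GEMMs are
// arranged accordingly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gather image patches into an (oh*ow) x (C*kh*kw) matrix. Output
// position (r, c) maps to row r + c*oh; source pixel is
// (r*stride + ki - pt, c*stride + kj - pl), zero outside the image.
static arma::mat im2col_t(const arma::cube& x, int kh, int kw, int stride,
                          int pt, int pl, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat K((size_t)oh * ow, C * kh * kw, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* sl = x.slice_memptr(c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        double* kcol = K.colptr((c * kh + ki) * kw + kj);
        for (int oc_ = 0; oc_ < ow; ++oc_) {
          const int iw = oc_ * stride + kj - pl;
          if (iw < 0 || iw >= W) continue;
          const double* src = sl + (size_t)iw * H;
          double* dst = kcol + (size_t)oc_ * oh;
          const int i0 = std::max(0, (pt - ki + stride - 1) / stride);
          for (int orr = i0; orr < oh; ++orr) {
            const int ih = orr * stride + ki - pt;
            if (ih >= H) break;
            dst[orr] = src[ih];
          }
        }
      }
    }
  }
  return K;
}

// Adjoint of im2col_t: scatter-add patch rows back into an image.
static arma::cube col2im_t(const arma::mat& K, int H, int W, int C,
                           int kh, int kw, int stride, int pt, int pl,
                           int oh, int ow) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* sl = x.slice_memptr(c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const double* kcol = K.colptr((c * kh + ki) * kw + kj);
        for (int oc_ = 0; oc_ < ow; ++oc_) {
          const int iw = oc_ * stride + kj - pl;
          if (iw < 0 || iw >= W) continue;
          double* dst = sl + (size_t)iw * H;
          const double* src = kcol + (size_t)oc_ * oh;
          const int i0 = std::max(0, (pt - ki + stride - 1) / stride);
          for (int orr = i0; orr < oh; ++orr) {
            const int ih = orr * stride + ki - pt;
            if (ih >= H) break;
            dst[ih] += src[orr];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int kh, int kw, int stride,
                        int pt, int pl, int oh, int ow) {
  arma::mat K = im2col_t(x, kh, kw, stride, pt, pl, oh, ow);
  arma::mat Y = K * W.t();          // (oh*ow) x OC
  Y.each_row() += b.t();
  const int OC = W.n_rows;
  arma::cube out(oh, ow, OC);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& W,
                  const arma::cube& gy, int kh, int kw, int stride,
                  int pt, int pl) {
  const int oh = gy.n_rows, ow = gy.n_cols, OC = gy.n_slices;
  arma::mat G((size_t)oh * ow, OC);
  std::memcpy(G.memptr(), gy.memptr(), sizeof(double) * gy.n_elem);
  arma::mat K = im2col_t(x, kh, kw, stride, pt, pl, oh, ow);
  arma::mat gW = G.t() * K;         // OC x (C*kh*kw)
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gK = G * W;             // (oh*ow) x (C*kh*kw)
  arma::cube gx = col2im_t(gK, x.n_rows, x.n_cols, x.n_slices,
                           kh, kw, stride, pt, pl, oh, ow);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution. Geometry: an output of size (oh, ow) relates to
// the input of size (H, W) exactly as a forward conv with
// (kh, kw, stride, pt, pl) maps (oh, ow) down to (H, W).
// [[Rcpp::export]]
arma::cube cpp_deconv_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pt, int pl, int oh, int ow) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int OC = W.n_cols / (kh * kw);
  arma::mat X((size_t)H * Wd, C);
  std::memcpy(X.memptr(), x.memptr(), sizeof(double) * x.n_elem);
  arma::mat cols = X * W;           // (H*Wd) x (OC*kh*kw)
  arma::cube out = col2im_t(cols, oh, ow, OC, kh, kw, stride, pt, pl, H, Wd);
  for (int c = 0; c < OC; ++c) out.slice(c) += b(c);
  return out;
}

// [[Rcpp::export]]
List cpp_deconv_bwd(const arma::cube& x, const arma::mat& W,
                    const arma::cube& gy, int kh, int kw, int stride,
                    int pt, int pl) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int OC = gy.n_slices;
  arma::mat X((size_t)H * Wd, C);
  std::memcpy(X.memptr(), x.memptr(), sizeof(double) * x.n_elem);
  arma::mat Kg = im2col_t(gy, kh, kw, stride, pt, pl, H, Wd);
  arma::mat gX = Kg * W.t();        // (H*Wd) x C
  arma::cube gx(H, Wd, C);
  std::memcpy(gx.memptr(), gX.memptr(), sizeof(double) * gX.n_elem);
  arma::mat gW = X.t() * Kg;        // C x (OC*kh*kw)
  arma::vec gb(OC);
  for (int c = 0; c < OC; ++c) gb(c) = arma::accu(gy.slice(c));
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
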