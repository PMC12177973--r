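// Shared raster operations: resizing, affine warping, separable Gaussian
// blur, boundary extraction and Hausdorff distance between point sets.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Bilinear resize; sample positions use the pixel-center (align corners
// = FALSE) convention so constant images stay constant.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(oh, ow, C);
  const double sr = (double)H / oh, sc = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      double fc = (j + 0.5) * sc - 0.5;
      int c0 = (int)std::floor(fc);
      double wc = fc - c0;
      int c1 = std::min(std::max(c0 + 1, 0), W - 1);
      c0 = std::min(std::max(c0, 0), W - 1);
      for (int i = 0; i < oh; ++i) {
        double fr = (i + 0.5) * sr - 0.5;
        int r0 = (int)std::floor(fr);
        double wr = fr - r0;
        int r1 = std::min(std::max(r0 + 1, 0), H - 1);
        r0 = std::min(std::max(r0, 0), H - 1);
        out(i, j, c) =
          (1 - wr) * ((1 - wc) * x(r0, c0, c) + wc * x(r0, c1, c)) +
          wr * ((1 - wc) * x(r1, c0, c) + wc * x(r1, c1, c));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_resize_nearest(const IntegerMatrix& x, int oh, int ow) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix out(oh, ow);
  const double sr = (double)H / oh, sc = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    int cs = std::min((int)std::floor((j + 0.5) * sc), W - 1);
    for (int i = 0; i < oh; ++i) {
      int rs = std::min((int)std::floor((i + 0.5) * sr), H - 1);
      out(i, j) = x(rs, cs);
    }
  }
  return out;
}

// Affine warp with inverse mapping: source = A %*% c(r_dst, c_dst, 1).
// A is 2x3 in (row, col) coordinates. method 0 = nearest, 1 = bilinear.
// [[Rcpp::export]]
arma::cube cpp_warp_affine(const arma::cube& x, const arma::mat& A,
                           int oh, int ow, int method, double fill) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(oh, ow, C);
  out.fill(fill);
  for (int j = 0; j < ow; ++j) {
    for (int i = 0; i < oh; ++i) {
      const double sr = A(0, 0) * i + A(0, 1) * j + A(0, 2);
      const double sc = A(1, 0) * i + A(1, 1) * j + A(1, 2);
      if (method == 0) {
        const int r = (int)std::lround(sr), c = (int)std::lround(sc);
        if (r >= 0 && r < H && c >= 0 && c < W)
          for (int ch = 0; ch < C; ++ch) out(i, j, ch) = x(r, c, ch);
      } else {
        if (sr < -0.5 || sr > H - 0.5 || sc < -0.5 || sc > W - 0.5) continue;
        int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double wr = sr - r0, wc = sc - c0;
        int r1 = std::min(std::max(r0 + 1, 0), H - 1);
        int c1 = std::min(std::max(c0 + 1, 0), W - 1);
        r0 = std::min(std::max(r0, 0), H - 1);
        c0 = std::min(std::max(c0, 0), W - 1);
        for (int ch = 0; ch < C; ++ch)
          out(i, j, ch) =
            (1 - wr) * ((1 - wc) * x(r0, c0, ch) + wc * x(r0, c1, ch)) +
            wr * ((1 - wc) * x(r1, c0, ch) + wc * x(r1, c1, ch));
      }
    }
  }
  return out;
}

// Separable Gaussian blur with reflective borders. sigma <= 0 is identity.
// [[Rcpp::export]]
arma::cube cpp_gaussian_blur(const arma::cube& x, double sigma) {
  if (sigma <= 0) return x;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k(i + rad) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= arma::accu(k);
  arma::cube tmp(H, W, C), out(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t)
          s += k(t + rad) * x(reflect_idx(i + t, H), j, c);
        tmp(i, j, c) = s;
      }
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0;
        for (int t = -rad; t <= rad; ++t)
          s += k(t + rad) * tmp(i, reflect_idx(j + t, W), c);
        out(i, j, c) = s;
      }
  }
  return out;
}

// Boundary pixels: foreground with at least one background 4-neighbour;
// pixels outside the image count as background.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_mask(const IntegerMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0) continue;
      bool bg = (i == 0 || m(i - 1, j) == 0) ||
                (i == H - 1 || m(i + 1, j) == 0) ||
                (j == 0 || m(i, j - 1) == 0) ||
                (j == W - 1 || m(i, j + 1) == 0);
      if (bg) out(i, j) = 1;
    }
  return out;
}

// Symmetric Hausdorff distance between two point sets (rows = points).
// [[Rcpp::export]]
double cpp_hausdorff(const arma::mat& a, const arma::mat& b) {
  double hab = 0;
  for (arma::uword i = 0; i < a.n_rows; ++i) {
    double dmin = arma::datum::inf;
    for (arma::uword j = 0; j < b.n_rows; ++j) {
      const double dr = a(i, 0) - b(j, 0), dc = a(i, 1) - b(j, 1);
      const double d = dr * dr + dc * dc;
      if (d < dmin) dmin = d;
    }
    if (dmin > hab) hab = dmin;
  }
  double hba = 0;
  for (arma::uword j = 0; j < b.n_rows; ++j) {
    double dmin = arma::datum::inf;
    for (arma::uword i = 0; i < a.n_rows; ++i) {
      const double dr = a(i, 0) - b(j, 0), dc = a(i, 1) - b(j, 1);
      const double d = dr * dr + dc * dc;
      if (d < dmin) dmin = d;
    }
    if (dmin > hba) hba = dmin;
  }
  return std::sqrt(std::max(hab, hba));
}
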