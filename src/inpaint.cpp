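// Classical inpainting backends. Both start from an onion-peel fill that
// propagates known pixel values inward layer by layer (each unknown pixel
// takes the mean of its already-known 8-neighbours). The diffusion
// backend then relaxes the masked region to the harmonic (Laplace)
// solution with Dirichlet boundary values by successive over-relaxation.
// Only masked pixels are ever written.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::cube cpp_inpaint(const arma::cube& img, const IntegerMatrix& mask,
                       int refine, int max_iter, double tol, double omega) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube out = img;
  IntegerMatrix known(H, W);
  std::vector<std::pair<int, int>> unknown;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      known(i, j) = mask(i, j) == 0 ? 1 : 0;
      if (!known(i, j)) unknown.push_back({i, j});
    }
  if (unknown.empty()) return out;

  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // Onion-peel initial fill.
  std::vector<std::pair<int, int>> frontier = unknown;
  while (!frontier.empty()) {
    std::vector<std::pair<int, int>> next;
    std::vector<std::pair<int, int>> filled;
    for (const auto& p : frontier) {
      const int i = p.first, j = p.second;
      if (known(i, j)) continue;
      double wsum = 0;
      arma::vec val(C, arma::fill::zeros);
      for (int t = 0; t < 8; ++t) {
        const int ni = i + di[t], nj = j + dj[t];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        if (!known(ni, nj)) continue;
        const double w = (t == 1 || t == 3 || t == 4 || t == 6) ? 1.0 : 0.7071;
        wsum += w;
        for (int c = 0; c < C; ++c) val(c) += w * out(ni, nj, c);
      }
      if (wsum > 0) {
        for (int c = 0; c < C; ++c) out(i, j, c) = val(c) / wsum;
        filled.push_back(p);
      } else {
        next.push_back(p);
      }
    }
    if (filled.empty()) break;  // isolated region with no known support
    for (const auto& p : filled) known(p.first, p.second) = 1;
    frontier = next;
  }

  if (!refine) return out;

  // SOR relaxation to the harmonic fill over the masked set.
  for (int it = 0; it < max_iter; ++it) {
    double dmax = 0;
    for (const auto& p : unknown) {
      const int i = p.first, j = p.second;
      int n = 0;
      for (int c = 0; c < C; ++c) {
        double s = 0;
        n = 0;
        if (i > 0)     { s += out(i - 1, j, c); ++n; }
        if (i < H - 1) { s += out(i + 1, j, c); ++n; }
        if (j > 0)     { s += out(i, j - 1, c); ++n; }
        if (j < W - 1) { s += out(i, j + 1, c); ++n; }
        if (n == 0) continue;
        const double target = s / n;
        const double d = target - out(i, j, c);
        out(i, j, c) += omega * d;
        if (std::fabs(d) > dmax) dmax = std::fabs(d);
      }
    }
    if (dmax < tol) break;
  }
  return out;
}
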