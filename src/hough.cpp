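// Hough circle transform: Sobel gradients, gradient-directed centre
// voting over a radius range, perimeter-normalised accumulator scores,
// and greedy non-maximum suppression. The classical non-learning
// baseline for fiducial marker detection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_hough_circles(const arma::mat& gray, int rmin, int rmax,
                                double edge_rel, double sensitivity,
                                double min_dist) {
  const int H = gray.n_rows, W = gray.n_cols;
  arma::mat gx(H, W, arma::fill::zeros), gy(H, W, arma::fill::zeros);
  for (int j = 1; j < W - 1; ++j)
    for (int i = 1; i < H - 1; ++i) {
      // Sobel in (row, col): gy = d/drow, gx = d/dcol
      gy(i, j) = (gray(i + 1, j - 1) + 2 * gray(i + 1, j) + gray(i + 1, j + 1)) -
                 (gray(i - 1, j - 1) + 2 * gray(i - 1, j) + gray(i - 1, j + 1));
      gx(i, j) = (gray(i - 1, j + 1) + 2 * gray(i, j + 1) + gray(i + 1, j + 1)) -
                 (gray(i - 1, j - 1) + 2 * gray(i, j - 1) + gray(i + 1, j - 1));
    }
  arma::mat mag = arma::sqrt(gx % gx + gy % gy);
  const double thr = edge_rel * mag.max();
  if (!(thr > 0)) return NumericMatrix(0, 4);

  const int nr = rmax - rmin + 1;
  std::vector<arma::mat> acc(nr, arma::mat(H, W, arma::fill::zeros));
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mag(i, j) < thr) continue;
      const double ur = gy(i, j) / mag(i, j), uc = gx(i, j) / mag(i, j);
      for (int r = rmin; r <= rmax; ++r) {
        for (int s = -1; s <= 1; s += 2) {
          const int ci = (int)std::lround(i + s * r * ur);
          const int cj = (int)std::lround(j + s * r * uc);
          if (ci >= 0 && ci < H && cj >= 0 && cj < W)
            acc[r - rmin](ci, cj) += 1.0;
        }
      }
    }

  // Smooth each radius plane slightly (3x3 box) to pool rounding spread.
  for (int r = 0; r < nr; ++r) {
    arma::mat sm(H, W, arma::fill::zeros);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W) s += acc[r](ii, jj);
          }
        sm(i, j) = s;
      }
    acc[r] = sm / (2.0 * M_PI * (r + rmin));  // fraction of perimeter support
  }

  std::vector<std::array<double, 4>> cand;  // row, col, r, score
  for (int r = 0; r < nr; ++r)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        if (acc[r](i, j) >= sensitivity)
          cand.push_back({(double)i, (double)j, (double)(r + rmin),
                          acc[r](i, j)});
  std::sort(cand.begin(), cand.end(),
            [](const std::array<double, 4>& a, const std::array<double, 4>& b) {
              return a[3] > b[3];
            });
  std::vector<std::array<double, 4>> keep;
  for (const auto& c : cand) {
    bool ok = true;
    for (const auto& k : keep) {
      const double dr = c[0] - k[0], dc = c[1] - k[1];
      if (dr * dr + dc * dc < min_dist * min_dist) { ok = false; break; }
    }
    if (ok) keep.push_back(c);
  }
  NumericMatrix out(keep.size(), 4);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = keep[i][j];
  return out;
}
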