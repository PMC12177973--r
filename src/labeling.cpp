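// Connected-component labelling with 4- or 8-connectivity.
// Labels are assigned in first-encounter raster-scan order (rows scanned
// top to bottom, columns left to right within a row), so the result is
// deterministic.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& m, int connectivity) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qi((size_t)H * W), qj((size_t)H * W);
  int next = 0;
  const int n8i[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int n8j[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int n4i[4] = {-1, 0, 0, 1};
  const int n4j[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (m(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qi[tail] = i; qj[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        const int ci = qi[head], cj = qj[head]; ++head;
        for (int t = 0; t < nn; ++t) {
          const int ni = ci + (nn == 8 ? n8i[t] : n4i[t]);
          const int nj = cj + (nn == 8 ? n8j[t] : n4j[t]);
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (m(ni, nj) == 0 || lab(ni, nj) != 0) continue;
          lab(ni, nj) = next;
          qi[tail] = ni; qj[tail] = nj; ++tail;
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
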