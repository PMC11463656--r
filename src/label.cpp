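#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Breadth-first connected-component labelling of a binary matrix.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal neighbours).
// Labels are assigned in raster order of the first pixel encountered.
// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& mask, const int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int nn = connectivity;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  std::vector<int> qi(static_cast<size_t>(H) * W);
  std::vector<int> qj(static_cast<size_t>(H) * W);
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qi[tail] = i; qj[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        const int ci = qi[head], cj = qj[head]; ++head;
        for (int k = 0; k < nn; ++k) {
          const int ni = ci + dr[k], nj = cj + dc[k];
          if (ni >= 0 && ni < H && nj >= 0 && nj < W &&
              mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi[tail] = ni; qj[tail] = nj; ++tail;
          }
        }
      }
    }
  }
  return lab;
}
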