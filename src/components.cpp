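#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a 0/1 integer matrix (flood fill)
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix binary) {
  int nr = binary.nrow(), nc = binary.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      if (binary(r, c) == 0 || lab(r, c) != 0) continue;
      next_label++;
      stack.push_back(c * nr + r);
      lab(r, c) = next_label;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; dc++) {
          for (int dr = -1; dr <= 1; dr++) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (binary(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next_label;
              stack.push_back(c2 * nr + r2);
            }
          }
        }
      }
    }
  }
  return lab;
}
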