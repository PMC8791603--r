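#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a logical mask by iterative flood
// fill.  Provisional labels follow column-major scan order of the first
// pixel of each component; callers re-order them by (frame_min, arc_min).
// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next_label = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      lab(i, j) = next_label;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          const int qj = pj + dj;
          if (qj < 0 || qj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di;
            if (qi < 0 || qi >= nr) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next_label;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
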