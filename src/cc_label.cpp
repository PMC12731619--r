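#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary image.
//
// Components are maximal sets of true pixels connected under 4- or
// 8-neighbourhood. Labels are assigned consecutively (1..K) in raster order
// (row-major, top-left origin) of each component's first pixel, so the
// labeling is deterministic for a fixed input.
//
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix bin, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!bin(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx / nc, cc = idx % nc;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (bin(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}
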