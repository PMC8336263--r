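#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling by iterative flood fill.
// Returns an integer matrix: 0 = background, 1..k = component id
// (ids assigned in column-major scan order of first contact).
// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = cur;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning to a 1-pixel-wide, 8-connected skeleton.
// Pixels outside the image count as background.
// [[Rcpp::export]]
LogicalMatrix thin_mask_cpp(LogicalMatrix input) {
  const int nr = input.nrow(), nc = input.ncol();
  std::vector<char> img(static_cast<size_t>(nr) * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + static_cast<size_t>(j) * nr] = input(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[i + static_cast<size_t>(j) * nr];
  };

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + static_cast<size_t>(j) * nr]) continue;
          // neighbours clockwise from north
          const int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          const int p4 = at(i,     j + 1), p5 = at(i + 1, j + 1);
          const int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          const int p8 = at(i,     j - 1), p9 = at(i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                        (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                        (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                        (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (int p : kill) img[p] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + static_cast<size_t>(j) * nr] != 0;
  return out;
}
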