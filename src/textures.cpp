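#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level texture matrix accumulation. `levels` is an integer matrix with
// 0 outside the ROI and 1..ng inside; `offsets` is a k x 2 integer matrix of
// (drow, dcol) displacement vectors (one per direction).

// [[Rcpp::export(name = ".glcm_counts")]]
NumericMatrix glcm_counts(IntegerMatrix levels, int ng, IntegerMatrix offsets) {
  int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix P(ng, ng);
  for (int k = 0; k < offsets.nrow(); ++k) {
    int dr = offsets(k, 0), dc = offsets(k, 1);
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int a = levels(r, c);
        if (a == 0) continue;
        int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int b = levels(r2, c2);
        if (b == 0) continue;
        // symmetrized: count the pair in both orders
        P(a - 1, b - 1) += 1.0;
        P(b - 1, a - 1) += 1.0;
      }
    }
  }
  return P;
}

// Run-length counts pooled over directions; runs are broken by the mask.
// [[Rcpp::export(name = ".rlm_counts")]]
IntegerMatrix rlm_counts(IntegerMatrix levels, int ng, IntegerMatrix offsets) {
  int nr = levels.nrow(), nc = levels.ncol();
  int lmax = std::max(nr, nc);
  IntegerMatrix R(ng, lmax);
  for (int k = 0; k < offsets.nrow(); ++k) {
    int dr = offsets(k, 0), dc = offsets(k, 1);
    for (int r0 = 0; r0 < nr; ++r0) {
      for (int c0 = 0; c0 < nc; ++c0) {
        // start of a line: no in-bounds predecessor along (dr, dc)
        int rp = r0 - dr, cp = c0 - dc;
        if (rp >= 0 && rp < nr && cp >= 0 && cp < nc) continue;
        int r = r0, c = c0, cur = 0, len = 0;
        while (r >= 0 && r < nr && c >= 0 && c < nc) {
          int v = levels(r, c);
          if (v == cur) {
            if (v != 0) ++len;
          } else {
            if (cur != 0) R(cur - 1, len - 1) += 1;
            cur = v;
            len = (v != 0) ? 1 : 0;
          }
          r += dr; c += dc;
        }
        if (cur != 0) R(cur - 1, len - 1) += 1;
      }
    }
  }
  return R;
}

// Size-zone counts: zones are 8-connected components of equal gray level.
// [[Rcpp::export(name = ".szm_counts")]]
IntegerMatrix szm_counts(IntegerMatrix levels, int ng) {
  int nr = levels.nrow(), nc = levels.ncol();
  std::vector<char> seen(nr * nc, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  std::vector<int> stack;
  int smax = 1;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int idx = r + c * nr;
      int g = levels(r, c);
      if (g == 0 || seen[idx]) continue;
      int size = 0;
      stack.clear();
      stack.push_back(idx);
      seen[idx] = 1;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        ++size;
        int cr = cur % nr, cc = cur / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            int idx2 = r2 + c2 * nr;
            if (!seen[idx2] && levels(r2, c2) == g) {
              seen[idx2] = 1;
              stack.push_back(idx2);
            }
          }
        }
      }
      zones.push_back(std::make_pair(g, size));
      if (size > smax) smax = size;
    }
  }
  IntegerMatrix S(ng, smax);
  for (size_t i = 0; i < zones.size(); ++i)
    S(zones[i].first - 1, zones[i].second - 1) += 1;
  return S;
}
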