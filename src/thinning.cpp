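#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen iterative thinning on a 0/1 integer matrix; pixels outside the
// matrix are background (equivalent to padding with a background border).
//
// Each sub-iteration examines only "dirty" pixels - those whose
// 8-neighbourhood changed since that sub-iteration last examined them
// (initially every foreground pixel). Deletions are computed from the
// frozen state of the sub-iteration and applied together, so the result is
// identical to the full-scan formulation.

static inline int px(const std::vector<int> &m, int nr, int nc, int r, int c) {
  if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
  return m[r + (size_t)c * nr];
}

// [[Rcpp::export(name = ".zhang_suen_thin")]]
IntegerMatrix zhang_suen_thin(IntegerMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  const size_t n = (size_t)nr * nc;
  std::vector<int> cur(img.begin(), img.end());
  std::vector<char> dirty[2];
  dirty[0].assign(n, 0);
  dirty[1].assign(n, 0);
  std::vector<size_t> list[2], next_list, dels;
  for (size_t i = 0; i < n; ++i) {
    if (cur[i]) {
      dirty[0][i] = dirty[1][i] = 1;
      list[0].push_back(i);
      list[1].push_back(i);
    }
  }
  bool any = true;
  while (any) {
    any = false;
    for (int sub = 0; sub < 2; ++sub) {
      dels.clear();
      for (size_t idx : list[sub]) {
        dirty[sub][idx] = 0;
        if (!cur[idx]) continue;
        int r = (int)(idx % nr), c = (int)(idx / nr);
        int p2 = px(cur, nr, nc, r - 1, c),     p3 = px(cur, nr, nc, r - 1, c + 1);
        int p4 = px(cur, nr, nc, r,     c + 1), p5 = px(cur, nr, nc, r + 1, c + 1);
        int p6 = px(cur, nr, nc, r + 1, c),     p7 = px(cur, nr, nc, r + 1, c - 1);
        int p8 = px(cur, nr, nc, r,     c - 1), p9 = px(cur, nr, nc, r - 1, c - 1);
        int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (b < 2 || b > 6) continue;
        int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
        if (a != 1) continue;
        if (sub == 0) {
          if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
        } else {
          if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
        }
        dels.push_back(idx);
      }
      list[sub].clear();
      if (!dels.empty()) any = true;
      for (size_t idx : dels) cur[idx] = 0;
      // deletions invalidate both sub-iterations for all 8 neighbours
      for (size_t idx : dels) {
        int r = (int)(idx % nr), c = (int)(idx / nr);
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            size_t j = rr + (size_t)cc * nr;
            if (!cur[j]) continue;
            for (int s = 0; s < 2; ++s) {
              if (!dirty[s][j]) {
                dirty[s][j] = 1;
                if (s == sub) next_list.push_back(j);
                else list[s].push_back(j);
              }
            }
          }
        }
      }
      if (sub == 1 && !next_list.empty()) {
        // entries flagged for sub-iteration 2 while it was running
        list[1].insert(list[1].end(), next_list.begin(), next_list.end());
      }
      if (sub == 0 && !next_list.empty())
        list[0].insert(list[0].end(), next_list.begin(), next_list.end());
      next_list.clear();
    }
    if (list[0].empty() && list[1].empty()) break;
  }
  IntegerMatrix out(nr, nc);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}
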