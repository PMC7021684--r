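// Exact branch-and-bound for item-disjoint, category-balanced pair
// selection. Objective: lexicographically maximize (minimum per-category
// count, total count) over all item-disjoint subsets of the candidates.
// Candidates arrive in a fixed order; among equally optimal solutions the
// first one found (a greedy round-robin incumbent, then depth-first order
// preferring inclusion of earlier candidates) is kept, so the result is
// deterministic.
#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <vector>
using namespace Rcpp;

namespace {

struct Search {
  int n, k, maxpos, pos_total;
  std::vector<int> A, B, cat;           // cat: 0..k-1, or -1 (not balanced)
  std::vector<std::vector<int>> suffix; // (n+1) x k
  std::vector<char> used, cur_sel, best_sel;
  std::vector<int> counts;
  int used_count, best_min, best_total;

  void leaf(int total) {
    int m = 0;
    if (k > 0) m = *std::min_element(counts.begin(), counts.end());
    if (m > best_min || (m == best_min && total > best_total)) {
      best_min = m;
      best_total = total;
      best_sel = cur_sel;
    }
  }

  void rec(int i, int total) {
    if (i == n) {
      leaf(total);
      return;
    }
    int ub_min = 0;
    if (k > 0) {
      ub_min = INT_MAX;
      for (int c = 0; c < k; ++c)
        ub_min = std::min(ub_min, counts[c] + suffix[i][c]);
    }
    int ub_total = total + std::min(n - i, (pos_total - used_count) / 2);
    if (ub_min < best_min || (ub_min == best_min && ub_total <= best_total))
      return;
    int a = A[i], b = B[i];
    if (!used[a] && !used[b]) {
      used[a] = used[b] = 1;
      used_count += 2;
      if (cat[i] >= 0) ++counts[cat[i]];
      cur_sel[i] = 1;
      rec(i + 1, total + 1);
      cur_sel[i] = 0;
      if (cat[i] >= 0) --counts[cat[i]];
      used[a] = used[b] = 0;
      used_count -= 2;
    }
    rec(i + 1, total);
  }

  // Round-robin greedy (most-deficient balanced category first, then any
  // remaining feasible candidate) used as the initial incumbent.
  void greedy() {
    std::vector<char> g_used(maxpos + 1, 0), g_sel(n, 0);
    std::vector<int> g_counts(std::max(k, 1), 0);
    bool added = true;
    int total = 0;
    while (added && k > 0) {
      added = false;
      std::vector<int> order(k);
      for (int c = 0; c < k; ++c) order[c] = c;
      std::stable_sort(order.begin(), order.end(),
                       [&](int x, int y) { return g_counts[x] < g_counts[y]; });
      for (int oc = 0; oc < k; ++oc) {
        int c = order[oc];
        for (int i = 0; i < n; ++i) {
          if (g_sel[i] || cat[i] != c || g_used[A[i]] || g_used[B[i]]) continue;
          g_sel[i] = 1;
          g_used[A[i]] = g_used[B[i]] = 1;
          ++g_counts[c];
          ++total;
          added = true;
          break;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!g_sel[i] && cat[i] < 0 && !g_used[A[i]] && !g_used[B[i]]) {
        g_sel[i] = 1;
        g_used[A[i]] = g_used[B[i]] = 1;
        ++total;
      }
    }
    best_min = (k > 0) ? *std::min_element(g_counts.begin(),
                                           g_counts.begin() + k)
                       : 0;
    best_total = total;
    best_sel = g_sel;
  }
};

}  // namespace

// [[Rcpp::export(name = ".select_engine")]]
LogicalVector select_engine(IntegerVector item_a, IntegerVector item_b,
                            IntegerVector cat_index, int n_categories) {
  Search s;
  s.n = item_a.size();
  s.k = n_categories;
  s.A.assign(item_a.begin(), item_a.end());
  s.B.assign(item_b.begin(), item_b.end());
  s.cat.assign(cat_index.begin(), cat_index.end());
  s.maxpos = 0;
  for (int i = 0; i < s.n; ++i)
    s.maxpos = std::max(s.maxpos, std::max(s.A[i], s.B[i]));
  {
    std::vector<char> seen(s.maxpos + 1, 0);
    s.pos_total = 0;
    for (int i = 0; i < s.n; ++i) {
      if (!seen[s.A[i]]) { seen[s.A[i]] = 1; ++s.pos_total; }
      if (!seen[s.B[i]]) { seen[s.B[i]] = 1; ++s.pos_total; }
    }
  }
  s.suffix.assign(s.n + 1, std::vector<int>(std::max(s.k, 1), 0));
  for (int i = s.n - 1; i >= 0; --i) {
    s.suffix[i] = s.suffix[i + 1];
    if (s.cat[i] >= 0) ++s.suffix[i][s.cat[i]];
  }
  s.used.assign(s.maxpos + 1, 0);
  s.cur_sel.assign(s.n, 0);
  s.counts.assign(std::max(s.k, 1), 0);
  s.used_count = 0;
  s.greedy();
  s.rec(0, 0);
  LogicalVector out(s.n);
  for (int i = 0; i < s.n; ++i) out[i] = s.best_sel[i] != 0;
  return out;
}
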