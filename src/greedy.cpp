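#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Greedy marginal-loss cell removal (core-area Zonation family).
//
// Cells are removed one at a time, always the remaining candidate with the
// smallest marginal loss; per-species remaining totals Q_j are updated by
// subtraction after each removal (the same operation sequence the naive
// reference recomputation performs, so results are bit-identical).
//
// Marginal loss rules (w = species weight, v = feature value, Q = remaining
// species total; species with Q <= 0 contribute 0):
//   rule 0 (caz): delta_i = max_j w_j * v_ij / Q_j
//   rule 1 (abf): delta_i = sum_j w_j * v_ij / Q_j
//
// Hierarchy: `level` orders removal phases; all level-0 cells (free land) are
// removed before any level-1 cell (protected land), etc.
//
// Laziness: marginal losses only grow as Q shrinks, so a cached value is a
// valid lower bound. The heap top is re-evaluated before removal; on exact
// ties every candidate whose cached bound does not exceed the re-evaluated
// minimum is re-evaluated too, and the tie is broken by the lowest cell
// index, matching the naive oracle exactly.

struct Entry {
  double delta;
  int idx;
};
struct EntryCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.delta != b.delta) return a.delta > b.delta; // min-heap on delta
    return a.idx > b.idx;                             // then lowest index
  }
};

// [[Rcpp::export]]
IntegerVector greedy_order_cpp(NumericMatrix feat, NumericVector w,
                               IntegerVector level, int rule) {
  const int n = feat.nrow();
  const int S = feat.ncol();
  if (n == 0) stop("no cells to rank");

  // sparse per-cell storage (CSR)
  std::vector<int> start(n + 1, 0);
  {
    int nnz = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < S; ++j) if (feat(i, j) > 0) ++nnz;
      start[i + 1] = nnz;
    }
  }
  std::vector<int> sp(start[n]);
  std::vector<double> val(start[n]);
  {
    int k = 0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < S; ++j)
        if (feat(i, j) > 0) { sp[k] = j; val[k] = feat(i, j); ++k; }
  }

  std::vector<double> Q(S, 0.0);
  for (int j = 0; j < S; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += feat(i, j);
    Q[j] = s;
  }

  auto delta_of = [&](int i) -> double {
    double acc = 0.0;
    for (int k = start[i]; k < start[i + 1]; ++k) {
      const int j = sp[k];
      if (Q[j] > 0) {
        const double d = w[j] * val[k] / Q[j];
        if (rule == 0) { if (d > acc) acc = d; } else acc += d;
      }
    }
    return acc;
  };

  // removal phases by ascending level
  std::vector<int> levels_sorted(level.begin(), level.end());
  std::sort(levels_sorted.begin(), levels_sorted.end());
  levels_sorted.erase(std::unique(levels_sorted.begin(), levels_sorted.end()),
                      levels_sorted.end());

  IntegerVector order(n);
  int pos = 0;

  for (int lev : levels_sorted) {
    std::priority_queue<Entry, std::vector<Entry>, EntryCmp> heap;
    for (int i = 0; i < n; ++i)
      if (level[i] == lev) heap.push({delta_of(i), i});

    while (!heap.empty()) {
      Entry top = heap.top(); heap.pop();
      double d = delta_of(top.idx);

      // collect every candidate whose cached lower bound is <= d: any of them
      // could have true delta == d and a smaller index
      int best_idx = top.idx;
      double best_d = d;
      std::vector<Entry> back;
      while (!heap.empty() && heap.top().delta <= best_d) {
        Entry e = heap.top(); heap.pop();
        double de = delta_of(e.idx);
        if (de < best_d || (de == best_d && e.idx < best_idx)) {
          back.push_back({best_d, best_idx});
          best_d = de; best_idx = e.idx;
        } else {
          back.push_back({de, e.idx});
        }
      }
      // every popped candidate is now either `best` or sits in `back`
      // (each swap recorded the displaced incumbent), so push back the rest
      for (auto& e : back) heap.push(e);

      // remove best_idx
      order[pos++] = best_idx;
      for (int k = start[best_idx]; k < start[best_idx + 1]; ++k)
        Q[sp[k]] -= val[k];
    }
  }
  return order; // 0-based indices in removal order
}
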