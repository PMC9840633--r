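// Ward minimum-variance agglomeration by the nearest-neighbor-chain
// algorithm on a condensed distance vector. Works on squared distances with
// the Lance-Williams update; reported heights are on the distance scale
// (sqrt of the merge cost), matching the ward.D2 convention. Tie-break:
// within nearest-neighbor selection the smallest cluster index wins, and
// the final stable sort by height preserves merge order among ties.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t cidx(R_xlen_t n, R_xlen_t i, R_xlen_t j) {
  if (i > j) std::swap(i, j);
  return n * i - i * (i + 1) / 2 + j - i - 1;
}

// [[Rcpp::export(name = ".ward_nnchain_cpp")]]
List ward_nnchain_cpp(NumericVector d, int n_) {
  const R_xlen_t n = n_;
  if (n < 2) stop("need at least 2 observations");
  if (d.size() != n * (n - 1) / 2) stop("condensed length mismatch");
  for (R_xlen_t t = 0; t < d.size(); ++t)
    if (!R_finite(d[t])) stop("non-finite distance at condensed position %td", (ptrdiff_t)(t + 1));

  std::vector<double> s(d.begin(), d.end());
  for (auto& v : s) v *= v;              // squared distances
  std::vector<double> size(n, 1.0);
  std::vector<bool> active(n, true);
  std::vector<R_xlen_t> chain; chain.reserve(n);

  // raw merges: cluster labels are the surviving (smaller) member index
  std::vector<R_xlen_t> ma(n - 1), mb(n - 1);
  std::vector<double> cost(n - 1);
  R_xlen_t nmerge = 0, search_from = 0;

  while (nmerge < n - 1) {
    if (chain.empty()) {
      while (!active[search_from]) ++search_from;
      chain.push_back(search_from);
    }
    for (;;) {
      R_xlen_t a = chain.back();
      R_xlen_t prev = chain.size() >= 2 ? chain[chain.size() - 2] : -1;
      // nearest active neighbor of a; smallest index wins ties; prefer prev
      // on equal cost so reciprocal pairs terminate.
      R_xlen_t best = -1; double bestv = R_PosInf;
      if (prev >= 0) { best = prev; bestv = s[cidx(n, a, prev)]; }
      for (R_xlen_t k = 0; k < n; ++k) {
        if (!active[k] || k == a || k == prev) continue;
        double v = s[cidx(n, a, k)];
        // strictly smaller wins; on ties prev is never displaced (so
        // reciprocal pairs terminate), otherwise the smallest index wins
        if (v < bestv ||
            (v == bestv && best != prev && (best < 0 || k < best))) {
          best = k; bestv = v;
        }
      }
      if (best == prev && prev >= 0) {
        // reciprocal nearest neighbors: merge a and prev
        R_xlen_t x = std::min(a, prev), y = std::max(a, prev);
        double sab = s[cidx(n, x, y)];
        ma[nmerge] = x; mb[nmerge] = y; cost[nmerge] = sab; ++nmerge;
        double sx = size[x], sy = size[y];
        for (R_xlen_t k = 0; k < n; ++k) {
          if (!active[k] || k == x || k == y) continue;
          double sk = size[k];
          s[cidx(n, x, k)] = ((sx + sk) * s[cidx(n, x, k)] +
                              (sy + sk) * s[cidx(n, y, k)] -
                              sk * sab) / (sx + sy + sk);
        }
        size[x] = sx + sy; active[y] = false;
        chain.pop_back(); chain.pop_back();
        break;
      }
      chain.push_back(best);
    }
  }

  // stable sort by merge cost, then relabel to hclust codes via union-find
  std::vector<R_xlen_t> ord(n - 1);
  for (R_xlen_t i = 0; i < n - 1; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](R_xlen_t i, R_xlen_t j) { return cost[i] < cost[j]; });

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  std::vector<R_xlen_t> node(n, -1);   // leaf -> internal node owning it (1-based), -1 none
  std::vector<R_xlen_t> parent(n);     // union-find over surviving labels
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = i;
  std::function<R_xlen_t(R_xlen_t)> find = [&](R_xlen_t x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  for (R_xlen_t r = 0; r < n - 1; ++r) {
    R_xlen_t m = ord[r];
    R_xlen_t ra = find(ma[m]), rb = find(mb[m]);
    int ca = node[ra] < 0 ? -(int)(ra + 1) : (int)node[ra];
    int cb = node[rb] < 0 ? -(int)(rb + 1) : (int)node[rb];
    if ((ca < 0 && cb < 0 && -ca > -cb) || (ca > 0 && cb > 0 && ca > cb) ||
        (ca > 0 && cb < 0)) std::swap(ca, cb);  // hclust ordering convention
    merge(r, 0) = ca; merge(r, 1) = cb;
    height[r] = std::sqrt(cost[m]);
    parent[rb] = ra;
    node[ra] = r + 1;
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
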