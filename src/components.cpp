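#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct DSU {
  std::vector<int> parent, size;
  int max_size;
  explicit DSU(int n) : parent(n), size(n, 1), max_size(0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) {
      if (size[a] > max_size) max_size = size[a];
      return;
    }
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    if (size[a] > max_size) max_size = size[a];
  }
};

}  // namespace

// Edge-count and largest-connected-component curves over a grid of weight
// thresholds, for a weighted undirected graph given as an edge list.
// For each threshold c the subgraph keeps edges with weight >= c.
// Thresholds are scanned in decreasing order while edges (sorted by
// decreasing weight) are added incrementally to a union-find structure,
// so the whole curve costs one pass over the edges.
// ia/ja are 1-based node indices.
// [[Rcpp::export]]
List threshold_curves_cpp(IntegerVector ia, IntegerVector ja,
                          NumericVector w, int n_nodes,
                          NumericVector thresholds) {
  const int m = w.size(), nc = thresholds.size();
  std::vector<int> eord(m), cord(nc);
  for (int i = 0; i < m; ++i) eord[i] = i;
  for (int i = 0; i < nc; ++i) cord[i] = i;
  std::sort(eord.begin(), eord.end(),
            [&](int a, int b) { return w[a] > w[b]; });
  std::sort(cord.begin(), cord.end(),
            [&](int a, int b) { return thresholds[a] > thresholds[b]; });

  IntegerVector E(nc), C(nc);
  DSU dsu(n_nodes);
  int added = 0, ei = 0;
  for (int k = 0; k < nc; ++k) {
    double c = thresholds[cord[k]];
    while (ei < m && w[eord[ei]] >= c) {
      int e = eord[ei];
      dsu.unite(ia[e] - 1, ja[e] - 1);
      ++added;
      ++ei;
    }
    E[cord[k]] = added;
    C[cord[k]] = (added > 0) ? dsu.max_size : 0;
  }
  return List::create(_["edges"] = E, _["lcc"] = C);
}
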