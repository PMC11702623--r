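#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Meyer-style priority-flood watershed on a triangle mesh, seeded at local
// minima (plateau-connected minima share one seed). Vertices are flooded in
// increasing value order (ties broken by vertex index); a vertex whose
// already-labeled neighbours carry >= 2 distinct basin labels at flood time
// becomes boundary (label 0) and is excluded from every basin.
//
// ringStarts/ringIdx: flattened 0-based adjacency (CSR layout), ringStarts
// has V + 1 entries.
// [[Rcpp::export]]
List watershed_flood_cpp(NumericVector values, IntegerVector ringStarts,
                         IntegerVector ringIdx) {
  const int V = values.size();
  std::vector<int> label(V, -1);
  std::vector<bool> ismin(V, false);

  for (int v = 0; v < V; ++v) {
    bool mn = true;
    for (int k = ringStarts[v]; k < ringStarts[v + 1]; ++k)
      if (values[ringIdx[k]] < values[v]) { mn = false; break; }
    ismin[v] = mn;
  }

  int nb = 0;
  for (int v = 0; v < V; ++v) {
    if (!ismin[v] || label[v] != -1) continue;
    ++nb;
    std::vector<int> stack;
    stack.push_back(v);
    label[v] = nb;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int k = ringStarts[u]; k < ringStarts[u + 1]; ++k) {
        int w = ringIdx[k];
        if (ismin[w] && label[w] == -1 && values[w] == values[u]) {
          label[w] = nb;
          stack.push_back(w);
        }
      }
    }
  }

  typedef std::pair<double, int> PV;
  struct Cmp {
    bool operator()(const PV& a, const PV& b) const {
      if (a.first != b.first) return a.first > b.first;
      return a.second > b.second;
    }
  };
  std::priority_queue<PV, std::vector<PV>, Cmp> pq;
  std::vector<bool> queued(V, false);

  for (int v = 0; v < V; ++v) {
    if (label[v] == -1) continue;
    for (int k = ringStarts[v]; k < ringStarts[v + 1]; ++k) {
      int w = ringIdx[k];
      if (label[w] == -1 && !queued[w]) {
        pq.push(std::make_pair(values[w], w));
        queued[w] = true;
      }
    }
  }

  while (!pq.empty()) {
    int u = pq.top().second;
    pq.pop();
    if (label[u] != -1) continue;
    int l0 = 0;
    bool multi = false;
    for (int k = ringStarts[u]; k < ringStarts[u + 1]; ++k) {
      int lw = label[ringIdx[k]];
      if (lw > 0) {
        if (l0 == 0) l0 = lw;
        else if (lw != l0) multi = true;
      }
    }
    label[u] = multi ? 0 : l0;  // l0 == 0: reached only through boundary
    for (int k = ringStarts[u]; k < ringStarts[u + 1]; ++k) {
      int w = ringIdx[k];
      if (label[w] == -1 && !queued[w]) {
        pq.push(std::make_pair(values[w], w));
        queued[w] = true;
      }
    }
  }

  IntegerVector lab(V);
  LogicalVector boundary(V);
  for (int v = 0; v < V; ++v) {
    lab[v] = label[v];
    boundary[v] = (label[v] == 0);
  }
  return List::create(_["labels"] = lab, _["boundary"] = boundary,
                      _["n_basins"] = nb);
}
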