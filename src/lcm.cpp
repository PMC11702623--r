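#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double pearson(const double* x, const double* y, int n,
                             bool& defined) {
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) { defined = false; return 0.0; }
  defined = true;
  double r = sxy / std::sqrt(sxx * syy);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// Deformable local correlation for 1-ring patches: per centre, the maximum
// Pearson correlation over the vanilla candidate, +/- one cyclic ring
// rotation of the base patch, and translations of the base patch centre to
// each ring neighbour (rings are stored in cyclic order starting at the
// lowest-index neighbour). When a translation pairs patches of unequal
// length (hexagon vs pentagon) both are truncated to the shorter length.
// Candidates with a constant patch contribute 0; a centre is flagged when
// every candidate was undefined.
// [[Rcpp::export]]
List deformable_lcm_cpp(NumericVector tmap, NumericVector bmap,
                        IntegerVector centers, IntegerVector ringStarts,
                        IntegerVector ringIdx) {
  const int nC = centers.size();
  NumericVector out(nC);
  NumericVector vanilla(nC);
  LogicalVector flag(nC);
  std::vector<double> tp(8), bp(8);

  for (int c = 0; c < nC; ++c) {
    int v = centers[c] - 1;
    int s = ringStarts[v], e = ringStarts[v + 1];
    int deg = e - s;
    int n = deg + 1;
    tp[0] = tmap[v];
    for (int k = 0; k < deg; ++k) tp[k + 1] = tmap[ringIdx[s + k]];

    bool anyDefined = false, def;
    double best = R_NegInf;

    // vanilla
    bp[0] = bmap[v];
    for (int k = 0; k < deg; ++k) bp[k + 1] = bmap[ringIdx[s + k]];
    double r = pearson(tp.data(), bp.data(), n, def);
    if (def) anyDefined = true;
    vanilla[c] = def ? r : 0.0;
    double cand = def ? r : 0.0;
    if (cand > best) best = cand;

    // ring rotations of the base patch by +/- one step
    for (int rot = -1; rot <= 1; rot += 2) {
      bp[0] = bmap[v];
      for (int k = 0; k < deg; ++k) {
        int kk = ((k - rot) % deg + deg) % deg;
        bp[k + 1] = bmap[ringIdx[s + kk]];
      }
      r = pearson(tp.data(), bp.data(), n, def);
      if (def) anyDefined = true;
      cand = def ? r : 0.0;
      if (cand > best) best = cand;
    }

    // translations: base patch re-centred on each ring neighbour
    for (int d = 0; d < deg; ++d) {
      int u = ringIdx[s + d];
      int su = ringStarts[u], eu = ringStarts[u + 1];
      int degU = eu - su;
      int len = (deg < degU ? deg : degU) + 1;
      bp[0] = bmap[u];
      for (int k = 0; k < degU; ++k) bp[k + 1] = bmap[ringIdx[su + k]];
      r = pearson(tp.data(), bp.data(), len, def);
      if (def) anyDefined = true;
      cand = def ? r : 0.0;
      if (cand > best) best = cand;
    }

    out[c] = best;
    flag[c] = !anyDefined;
  }
  return List::create(_["values"] = out, _["vanilla"] = vanilla,
                      _["flags"] = flag);
}
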