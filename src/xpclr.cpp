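#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Window scoring for the XP-CLR-style scan on one chromosome.  Per grid
// point: member SNPs are those within half_width cM; scorable SNPs are the
// ones flagged usable (reference frequency strictly inside (0,1)).  LD
// weights are 1/k with k = 1 + (strong-LD partners inside the window),
// partners precomputed in R as the adjacency list `adj` (1-based indices).
// The composite log-likelihood-ratio sum is maximized over the sweep-scale
// grid and the no-sweep model; the returned CLR is twice that maximum.
// scale_idx is 1-based into `scales`, 0 meaning no-sweep optimal.
// [[Rcpp::export]]
List cpp_clr_chrom(NumericVector grid_cm, NumericVector snp_cm,
                   NumericVector logf0, NumericVector f0, NumericVector mix,
                   LogicalVector usable, List adj, NumericVector scales,
                   double half_width) {
  const int G = grid_cm.size(), M = snp_cm.size(), S = scales.size();
  NumericVector clr(G);
  IntegerVector scale_idx(G), n_snps(G);
  std::vector<double> w; w.reserve(64);
  std::vector<int> members; members.reserve(64);

  for (int g = 0; g < G; ++g) {
    const double gc = grid_cm[g];
    int lo = std::lower_bound(snp_cm.begin(), snp_cm.end(), gc - half_width)
             - snp_cm.begin();
    int hi = std::upper_bound(snp_cm.begin(), snp_cm.end(), gc + half_width)
             - snp_cm.begin() - 1;
    members.clear(); w.clear();
    for (int i = lo; i <= hi && i < M; ++i)
      if (usable[i]) members.push_back(i);
    n_snps[g] = members.size();
    if (members.empty()) { clr[g] = 0.0; scale_idx[g] = 0; continue; }
    for (size_t m = 0; m < members.size(); ++m) {
      IntegerVector nb = adj[members[m]];
      int k = 1;
      for (int j = 0; j < nb.size(); ++j) {
        int idx = nb[j] - 1;
        if (idx >= lo && idx <= hi) ++k;
      }
      w.push_back(1.0 / k);
    }
    double best = 0.0; int best_s = 0;
    for (int s = 0; s < S; ++s) {
      double ll = 0.0;
      for (size_t m = 0; m < members.size(); ++m) {
        const int i = members[m];
        const double d = std::abs(snp_cm[i] - gc);
        const double c = 1.0 - std::exp(-d / scales[s]);
        double f1 = c * f0[i] + (1.0 - c) * mix[i];
        if (f1 < 1e-300) f1 = 1e-300;
        ll += w[m] * (std::log(f1) - logf0[i]);
      }
      if (ll > best) { best = ll; best_s = s + 1; }
    }
    clr[g] = 2.0 * best;
    scale_idx[g] = best_s;
  }
  return List::create(_["clr"] = clr, _["scale_idx"] = scale_idx,
                      _["n_snps"] = n_snps);
}
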