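#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Chromosome block boundaries from a grouped chrom-id vector.
static void chrom_blocks(const IntegerVector& chrom_id,
                         std::vector<int>& starts, std::vector<int>& ends) {
  const int M = chrom_id.size();
  starts.clear(); ends.clear();
  int s = 0;
  for (int i = 1; i <= M; ++i) {
    if (i == M || chrom_id[i] != chrom_id[s]) {
      starts.push_back(s); ends.push_back(i - 1); s = i;
    }
  }
}

// One recombined gamete from the haplotype pair (h1, h2) of `panel`,
// written into row `orow` of `out`.  Crossovers are Poisson with mean
// = chromosome length in Morgans (cm/100), positions uniform in cM.
static void gamete(const IntegerMatrix& panel, int h1, int h2,
                   const NumericVector& cm,
                   const std::vector<int>& cstart,
                   const std::vector<int>& cend,
                   IntegerMatrix& out, int orow,
                   std::vector<double>& xpos) {
  for (size_t c = 0; c < cstart.size(); ++c) {
    const int lo = cstart[c], hi = cend[c];
    int cur = (unif_rand() < 0.5) ? h1 : h2;
    const double cm_lo = cm[lo], cm_hi = cm[hi];
    const double morgans = (cm_hi - cm_lo) / 100.0;
    const int ncx = (int) R::rpois(morgans);
    if (ncx == 0) {
      for (int i = lo; i <= hi; ++i) out(orow, i) = panel(cur, i);
      continue;
    }
    xpos.clear();
    for (int k = 0; k < ncx; ++k)
      xpos.push_back(cm_lo + unif_rand() * (cm_hi - cm_lo));
    std::sort(xpos.begin(), xpos.end());
    size_t nx = 0;
    for (int i = lo; i <= hi; ++i) {
      while (nx < xpos.size() && xpos[nx] < cm[i]) {
        cur = (cur == h1) ? h2 : h1;
        ++nx;
      }
      out(orow, i) = panel(cur, i);
    }
  }
}

// Wright-Fisher evolution of one line for `gens` generations at constant
// diploid size `ne`, starting from `panel` (2K haplotypes in rows; the
// initial generation is formed by random mating of the K implied diploids).
// Selection: each sweep locus multiplies a parent's sampling weight by
// (1+s) per copy of allele 1 (haploid-multiplicative fitness).
// [[Rcpp::export]]
IntegerMatrix cpp_wf_evolve(IntegerMatrix panel, int ne, int gens,
                            NumericVector cm, IntegerVector chrom_id,
                            IntegerVector sweep_idx, NumericVector s) {
  const int M = panel.ncol();
  if (panel.nrow() < 4) stop("need at least 2 founding diploids");
  if (panel.nrow() % 2 != 0) stop("panel must hold diploids (even rows)");
  std::vector<int> cstart, cend;
  chrom_blocks(chrom_id, cstart, cend);
  std::vector<double> xpos;

  IntegerMatrix cur = panel;
  for (int g = 0; g < gens; ++g) {
    const int npar = cur.nrow() / 2;
    std::vector<double> cw(npar);
    double tot = 0.0;
    for (int i = 0; i < npar; ++i) {
      double w = 1.0;
      for (int k = 0; k < sweep_idx.size(); ++k) {
        const int loc = sweep_idx[k];
        const int copies = cur(2 * i, loc) + cur(2 * i + 1, loc);
        for (int c = 0; c < copies; ++c) w *= (1.0 + s[k]);
      }
      tot += w;
      cw[i] = tot;
    }
    IntegerMatrix nxt(2 * ne, M);
    for (int k = 0; k < ne; ++k) {
      const double u1 = unif_rand() * tot, u2 = unif_rand() * tot;
      const int p1 = std::lower_bound(cw.begin(), cw.end(), u1) - cw.begin();
      const int p2 = std::lower_bound(cw.begin(), cw.end(), u2) - cw.begin();
      gamete(cur, 2 * p1, 2 * p1 + 1, cm, cstart, cend, nxt, 2 * k, xpos);
      gamete(cur, 2 * p2, 2 * p2 + 1, cm, cstart, cend, nxt, 2 * k + 1, xpos);
    }
    cur = nxt;
  }
  return cur;
}

// Founder-mosaic construction of a base panel: each output haplotype is a
// mosaic of the founder haplotypes with segment switches at Poisson
// crossover points (`depth` expected crossovers per Morgan, emulating the
// recombination accumulated while the base population mixed).
// [[Rcpp::export]]
IntegerMatrix cpp_founder_mosaic(IntegerMatrix founders, int n_hap,
                                 NumericVector cm, IntegerVector chrom_id,
                                 double depth) {
  const int F = founders.nrow(), M = founders.ncol();
  if (F < 2) stop("need at least 2 founder haplotypes");
  std::vector<int> cstart, cend;
  chrom_blocks(chrom_id, cstart, cend);
  IntegerMatrix out(n_hap, M);
  std::vector<double> xpos;

  for (int h = 0; h < n_hap; ++h) {
    for (size_t c = 0; c < cstart.size(); ++c) {
      const int lo = cstart[c], hi = cend[c];
      const double cm_lo = cm[lo], cm_hi = cm[hi];
      int cur = (int)(unif_rand() * F);
      const int ncx = (int) R::rpois(depth * (cm_hi - cm_lo) / 100.0);
      if (ncx == 0) {
        for (int i = lo; i <= hi; ++i) out(h, i) = founders(cur, i);
        continue;
      }
      xpos.clear();
      for (int k = 0; k < ncx; ++k)
        xpos.push_back(cm_lo + unif_rand() * (cm_hi - cm_lo));
      std::sort(xpos.begin(), xpos.end());
      size_t nx = 0;
      for (int i = lo; i <= hi; ++i) {
        while (nx < xpos.size() && xpos[nx] < cm[i]) {
          cur = (int)(unif_rand() * F);
          ++nx;
        }
        out(h, i) = founders(cur, i);
      }
    }
  }
  return out;
}
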