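#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Incremental site-EHH walk for every core SNP of one chromosome, over two
// haplotype panels sharing a marker set.  Group identity over the window
// [core..x] is tracked for the combined panel; the EHH of A, B and the
// joint sample fall out of the same partition because two haplotypes of A
// are identical over the window iff they share a combined group.  Both
// populations are truncated at the shared boundary: the first marker where
// the joint EHH drops below ehh_floor (the trapezoid segment reaching that
// marker is included), or the chromosome end.
//
// Returns an M x 2 matrix of (iHH_A, iHH_B) in cM units.
// [[Rcpp::export]]
NumericMatrix cpp_xpehh_chrom(IntegerMatrix hapA, IntegerMatrix hapB,
                              NumericVector cm, double ehh_floor) {
  const int nA = hapA.nrow(), nB = hapB.nrow(), n = nA + nB;
  const int M = hapA.ncol();
  if (hapB.ncol() != M) stop("panels must share the marker set");
  if (nA < 2 || nB < 2) stop("need >= 2 haplotypes per population");
  const double denA = 0.5 * nA * (nA - 1.0);
  const double denB = 0.5 * nB * (nB - 1.0);
  const double denC = 0.5 * n * (n - 1.0);

  NumericMatrix out(M, 2);
  std::vector<int> gid(n), remap(2 * n + 2);
  std::vector<int> cntA(n + 1), cntB(n + 1);

  for (int core = 0; core < M; ++core) {
    double ihhA = 0.0, ihhB = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      // partition at the core site
      int ngroups = 0;
      std::fill(remap.begin(), remap.begin() + 2, -1);
      for (int i = 0; i < n; ++i) {
        int a = (i < nA) ? hapA(i, core) : hapB(i - nA, core);
        if (remap[a] < 0) remap[a] = ngroups++;
        gid[i] = remap[a];
      }
      double eA = 0, eB = 0, eC = 0;
      {
        std::fill(cntA.begin(), cntA.begin() + ngroups, 0);
        std::fill(cntB.begin(), cntB.begin() + ngroups, 0);
        for (int i = 0; i < nA; ++i) cntA[gid[i]]++;
        for (int i = nA; i < n; ++i) cntB[gid[i]]++;
        double sA = 0, sB = 0, sC = 0;
        for (int g = 0; g < ngroups; ++g) {
          sA += 0.5 * cntA[g] * (cntA[g] - 1.0);
          sB += 0.5 * cntB[g] * (cntB[g] - 1.0);
          double c = cntA[g] + cntB[g];
          sC += 0.5 * c * (c - 1.0);
        }
        eA = sA / denA; eB = sB / denB; eC = sC / denC;
      }
      double prevA = eA, prevB = eB, prevC = eC, prev_cm = cm[core];
      int pos = core;
      while (prevC >= ehh_floor) {
        pos += dir;
        if (pos < 0 || pos >= M) break;
        // refine the partition with the allele at pos
        int newg = 0;
        std::fill(remap.begin(), remap.begin() + 2 * ngroups + 2, -1);
        for (int i = 0; i < n; ++i) {
          int a = (i < nA) ? hapA(i, pos) : hapB(i - nA, pos);
          int key = gid[i] * 2 + a;
          if (remap[key] < 0) remap[key] = newg++;
          gid[i] = remap[key];
        }
        ngroups = newg;
        std::fill(cntA.begin(), cntA.begin() + ngroups, 0);
        std::fill(cntB.begin(), cntB.begin() + ngroups, 0);
        for (int i = 0; i < nA; ++i) cntA[gid[i]]++;
        for (int i = nA; i < n; ++i) cntB[gid[i]]++;
        double sA = 0, sB = 0, sC = 0;
        for (int g = 0; g < ngroups; ++g) {
          sA += 0.5 * cntA[g] * (cntA[g] - 1.0);
          sB += 0.5 * cntB[g] * (cntB[g] - 1.0);
          double c = cntA[g] + cntB[g];
          sC += 0.5 * c * (c - 1.0);
        }
        eA = sA / denA; eB = sB / denB; eC = sC / denC;
        double d = std::abs(cm[pos] - prev_cm);
        ihhA += 0.5 * (prevA + eA) * d;
        ihhB += 0.5 * (prevB + eB) * d;
        prevA = eA; prevB = eB; prevC = eC; prev_cm = cm[pos];
      }
    }
    out(core, 0) = ihhA;
    out(core, 1) = ihhB;
  }
  return out;
}
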