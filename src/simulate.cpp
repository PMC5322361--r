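#include <Rcpp.h>
using namespace Rcpp;

// Forward-time copying-model simulator over ancestry tracts.
//
// Population states are indexed by generations before present. The state at
// generation g is formed from the state at g+1: each offspring haplotype is,
// with probability alpha1[g] / alpha2[g], a whole unadmixed migrant haplotype
// (single tract, label 1 or 2), and otherwise a recombinant of two random
// haplotypes of the previous state, with crossovers drawn as a Poisson
// process of rate 1 per Morgan. Migrants entering at generation l therefore
// experience exactly l recombination rounds before present-day sampling,
// matching the e^{-l d} basis used by the coefficient vectors.
// Chromosomes evolve independently (random mating; only within-chromosome
// LD is consumed downstream). Uses R's RNG, so set.seed() governs output.

struct Hap {
  std::vector<double> end;       // tract right ends, last == chromosome length
  std::vector<signed char> lab;  // ancestry per tract, 1 or 2
};

static inline void pushTract(Hap &h, double end, signed char lab) {
  if (!h.end.empty() && h.lab.back() == lab)
    h.end.back() = end;  // merge same-label junction
  else {
    h.end.push_back(end);
    h.lab.push_back(lab);
  }
}

// copy the portion (from, to] of parent tracts into child
static void copySegment(Hap &child, const Hap &par, double from, double to) {
  size_t i = std::lower_bound(par.end.begin(), par.end.end(), from) -
             par.end.begin();
  if (i >= par.end.size()) i = par.end.size() - 1;
  for (; i < par.end.size() && par.end[i] < to; ++i)
    if (par.end[i] > from) pushTract(child, par.end[i], par.lab[i]);
  if (i < par.end.size()) pushTract(child, to, par.lab[i]);
}

static Hap meiosis(const Hap &a, const Hap &b, double L) {
  int k = (int) R::rpois(L);
  if (k == 0) return (unif_rand() < 0.5) ? a : b;
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  Hap child;
  child.end.reserve(a.end.size() + b.end.size() + k);
  child.lab.reserve(a.end.size() + b.end.size() + k);
  bool useA = unif_rand() < 0.5;
  double from = 0.0;
  for (int i = 0; i <= k; ++i) {
    double to = (i == k) ? L : bp[i];
    if (to > from) copySegment(child, useA ? a : b, from, to);
    useA = !useA;
    from = to;
  }
  return child;
}

// [[Rcpp::export(name = ".simulate_tracts_cpp")]]
DataFrame simulate_tracts_cpp(NumericVector alpha1, NumericVector alpha2,
                              int founder, int popSize,
                              NumericVector chromLengths, int nSample) {
  const int gStart = alpha1.size();
  const int nChrom = chromLengths.size();
  std::vector<int> outChrom, outHap, outLab;
  std::vector<double> outStart, outEnd;

  for (int c = 0; c < nChrom; ++c) {
    const double L = chromLengths[c];
    std::vector<Hap> pop(popSize), nxt(popSize);
    for (int i = 0; i < popSize; ++i) {
      pop[i].end.assign(1, L);
      pop[i].lab.assign(1, (signed char) founder);
    }
    // form states at generations gStart, gStart-1, ..., 0
    for (int g = gStart; g >= 0; --g) {
      const double a1 = (g >= 1) ? alpha1[g - 1] : 0.0;
      const double a2 = (g >= 1) ? alpha2[g - 1] : 0.0;
      for (int i = 0; i < popSize; ++i) {
        double u = unif_rand();
        if (u < a1 || u < a1 + a2) {
          nxt[i].end.assign(1, L);
          nxt[i].lab.assign(1, (signed char) (u < a1 ? 1 : 2));
        } else {
          int pa = (int) (unif_rand() * popSize);
          int pb = (int) (unif_rand() * popSize);
          if (pa >= popSize) pa = popSize - 1;
          if (pb >= popSize) pb = popSize - 1;
          nxt[i] = meiosis(pop[pa], pop[pb], L);
        }
      }
      pop.swap(nxt);
    }
    for (int i = 0; i < nSample; ++i) {
      double from = 0.0;
      for (size_t t = 0; t < pop[i].end.size(); ++t) {
        outChrom.push_back(c + 1);
        outHap.push_back(i + 1);
        outStart.push_back(from);
        outEnd.push_back(pop[i].end[t]);
        outLab.push_back(pop[i].lab[t]);
        from = pop[i].end[t];
      }
    }
  }
  return DataFrame::create(_["chrom"] = outChrom, _["hap"] = outHap,
                           _["start"] = outStart, _["end"] = outEnd,
                           _["ancestry"] = outLab);
}

// Ancestry label of each (haplotype, site): tract rows must be sorted by
// chromosome, haplotype, start (as emitted by the simulator).
// [[Rcpp::export(name = ".ancestry_matrix_cpp")]]
IntegerMatrix ancestry_matrix_cpp(IntegerVector tChrom, IntegerVector tHap,
                                  NumericVector tStart, NumericVector tEnd,
                                  IntegerVector tLab, int nHap,
                                  NumericVector siteGpos,
                                  IntegerVector siteChrom) {
  const int nSite = siteGpos.size();
  IntegerMatrix out(nHap, nSite);
  // per-chromosome site index ranges (siteChrom sorted)
  int maxChrom = 0;
  for (int j = 0; j < nSite; ++j) if (siteChrom[j] > maxChrom) maxChrom = siteChrom[j];
  for (int r = 0; r < tChrom.size(); ++r) if (tChrom[r] > maxChrom) maxChrom = tChrom[r];
  std::vector<int> lo(maxChrom + 1, -1), hi(maxChrom + 1, -1);
  for (int j = 0; j < nSite; ++j) {
    int c = siteChrom[j];
    if (lo[c] < 0) lo[c] = j;
    hi[c] = j;
  }
  for (int r = 0; r < tChrom.size(); ++r) {
    int c = tChrom[r];
    if (lo[c] < 0) continue;
    // sites with start <= gpos < end (last tract takes gpos == end)
    const double s = tStart[r], e = tEnd[r];
    int jlo = lo[c], jhi = hi[c];
    // binary search for first site >= s
    int a = jlo, b = jhi + 1;
    while (a < b) { int m = (a + b) / 2; if (siteGpos[m] < s) a = m + 1; else b = m; }
    for (int j = a; j <= jhi && siteGpos[j] <= e; ++j) {
      if (siteGpos[j] < e || (r + 1 == tChrom.size()) ||
          tHap[r + 1] != tHap[r] || tChrom[r + 1] != c)
        out(tHap[r] - 1, j) = tLab[r];
    }
  }
  return out;
}
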