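#include <Rcpp.h>
using namespace Rcpp;

// Paint admixed haplotypes by copying, per ancestry tract, the allele
// slice of a donor haplotype from the matching source panel.  Tract rows
// must be sorted by chromosome, haplotype, start; sites by chromosome.
// [[Rcpp::export(name = ".copy_paint_cpp")]]
NumericMatrix copy_paint_cpp(IntegerVector tChrom, IntegerVector tHap,
                             NumericVector tStart, NumericVector tEnd,
                             IntegerVector tLab, IntegerVector donor,
                             int nHap, NumericMatrix src1, NumericMatrix src2,
                             NumericVector siteGpos, IntegerVector siteChrom) {
  const int nSite = siteGpos.size();
  NumericMatrix out(nHap, nSite);
  int maxChrom = 0;
  for (int j = 0; j < nSite; ++j) if (siteChrom[j] > maxChrom) maxChrom = siteChrom[j];
  std::vector<int> lo(maxChrom + 1, -1), hi(maxChrom + 1, -1);
  for (int j = 0; j < nSite; ++j) {
    int c = siteChrom[j];
    if (lo[c] < 0) lo[c] = j;
    hi[c] = j;
  }
  const R_xlen_t nTr = tChrom.size();
  for (R_xlen_t r = 0; r < nTr; ++r) {
    int c = tChrom[r];
    if (c > maxChrom || lo[c] < 0) continue;
    const double s = tStart[r], e = tEnd[r];
    const NumericMatrix &src = (tLab[r] == 1) ? src1 : src2;
    const int dn = (donor[r] - 1) % src.nrow();
    int a = lo[c], b = hi[c] + 1;
    while (a < b) { int m = (a + b) / 2; if (siteGpos[m] < s) a = m + 1; else b = m; }
    bool lastTract = (r + 1 == nTr) || tHap[r + 1] != tHap[r] || tChrom[r + 1] != c;
    for (int j = a; j <= hi[c] && siteGpos[j] <= e; ++j) {
      if (siteGpos[j] < e || lastTract)
        out(tHap[r] - 1, j) = src(dn, j);
    }
  }
  return out;
}
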