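#include <Rcpp.h>
using namespace Rcpp;

// Binned accumulation of cov(x,y) * delta[x] * delta[y] over same-chromosome
// site pairs, kept per chromosome so leave-one-chromosome-out curves are a
// subtraction rather than a recomputation. Covariance uses the unbiased
// (n-1) denominator; pairs with fewer than 4 complete observations are
// skipped. covScale rescales genotype-dosage covariance onto haplotype scale.
// [[Rcpp::export(name = ".ald_pair_accum")]]
List ald_pair_accum(NumericMatrix alleles, NumericVector gpos,
                    IntegerVector chromIdx, NumericVector delta,
                    double dmin, double dmax, double binWidth,
                    int nBins, int nChrom, double covScale) {
  const int nHap = alleles.nrow();
  const int nSite = alleles.ncol();
  NumericMatrix sum(nBins, nChrom);
  NumericMatrix cnt(nBins, nChrom);

  // complete-observation column sums for the fast no-missing path
  std::vector<double> colSum(nSite, 0.0);
  std::vector<int> colN(nSite, 0);
  bool anyNA = false;
  for (int j = 0; j < nSite; ++j) {
    double s = 0.0; int n = 0;
    for (int i = 0; i < nHap; ++i) {
      double v = alleles(i, j);
      if (NumericVector::is_na(v)) { anyNA = true; continue; }
      s += v; ++n;
    }
    colSum[j] = s; colN[j] = n;
  }

  for (int x = 0; x < nSite; ++x) {
    if (NumericVector::is_na(delta[x])) continue;
    const int cx = chromIdx[x] - 1;
    const double gx = gpos[x];
    for (int y = x + 1; y < nSite; ++y) {
      if (chromIdx[y] - 1 != cx) break;  // sites ordered by chromosome
      const double d = gpos[y] - gx;
      if (d < dmin) continue;
      if (d > dmax) break;               // gpos non-decreasing within chrom
      if (NumericVector::is_na(delta[y])) continue;
      int b = (int) std::floor((d - dmin) / binWidth);
      if (b >= nBins) b = nBins - 1;

      double sxy = 0.0, sx, sy; int n;
      if (!anyNA) {
        n = nHap;
        const double *ax = &alleles(0, x), *ay = &alleles(0, y);
        for (int i = 0; i < n; ++i) sxy += ax[i] * ay[i];
        sx = colSum[x]; sy = colSum[y];
      } else {
        n = 0; sx = 0.0; sy = 0.0;
        for (int i = 0; i < nHap; ++i) {
          double vx = alleles(i, x), vy = alleles(i, y);
          if (NumericVector::is_na(vx) || NumericVector::is_na(vy)) continue;
          sxy += vx * vy; sx += vx; sy += vy; ++n;
        }
      }
      if (n < 4) continue;
      double cov = (sxy - sx * sy / n) / (n - 1.0);
      sum(b, cx) += covScale * cov * delta[x] * delta[y];
      cnt(b, cx) += 1.0;
    }
  }
  return List::create(_["sum"] = sum, _["count"] = cnt);
}
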