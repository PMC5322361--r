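#include <Rcpp.h>
using namespace Rcpp;

// Bin the weighted products cov[x,y] * delta[x] * delta[y] of one
// chromosome's precomputed site-by-site covariance matrix.  gpos must be
// non-decreasing.  Sites with NA delta are skipped.
// [[Rcpp::export(name = ".cov_bin_accum")]]
List cov_bin_accum(NumericMatrix cv, NumericVector gpos, NumericVector delta,
                   double dmin, double dmax, double binWidth, int nBins) {
  const int p = cv.ncol();
  NumericVector sum(nBins), cnt(nBins);
  for (int x = 0; x < p; ++x) {
    if (NumericVector::is_na(delta[x])) continue;
    const double gx = gpos[x], dx = delta[x];
    const double *col; // column-major: use column y, row x (symmetric)
    for (int y = x + 1; y < p; ++y) {
      const double d = gpos[y] - gx;
      if (d < dmin) continue;
      if (d > dmax) break;
      if (NumericVector::is_na(delta[y])) continue;
      int b = (int) std::floor((d - dmin) / binWidth);
      if (b >= nBins) b = nBins - 1;
      col = &cv(0, y);
      sum[b] += col[x] * dx * delta[y];
      cnt[b] += 1.0;
    }
  }
  return List::create(_["sum"] = sum, _["count"] = cnt);
}
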