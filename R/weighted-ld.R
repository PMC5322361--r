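#' Distance-bin specification for weighted LD curves
#'
#' Pairs closer than `dMin` are excluded because background LD dominates at
#' very short range (default 0.5 cM); `dMax` defaults to 0.3 Morgans and the
#' bin width to 0.02 cM.
#'
#' @param dMin,dMax,binWidth distances in Morgans.
#' @return a list with the validated bin specification and the midpoint grid.
#' @export
binSpec <- function(dMin = 0.005, dMax = 0.3, binWidth = 2e-4) {
  stopifnot(0 < dMin, dMin < dMax, binWidth > 0)
  nBins <- ceiling((dMax - dMin) / binWidth - 1e-9)
  list(dMin = dMin, dMax = dMax, binWidth = binWidth, nBins = as.integer(nBins),
       mid = dMin + (seq_len(nBins) - 0.5) * binWidth)
}

#' Per-site weights from the two source panels
#'
#' delta[x] = p1(x) - p2(x), the sample allele-frequency difference between
#' source 1 and source 2 at site x.  Sites where either panel has no
#' observed alleles get NA (excluded downstream).
#'
#' @param source1,source2 aligned \linkS4class{HaplotypePanel}s.
#' @return numeric vector of weights in [-1, 1] (NA = excluded).
#' @export
siteWeights <- function(source1, source2) {
  stopifnot(is(source1, "HaplotypePanel"), is(source2, "HaplotypePanel"))
  if (nSites(source1) != nSites(source2) ||
      any(source1@chrom != source2@chrom) ||
      any(source1@gpos != source2@gpos))
    stop("source panels are not aligned on the same site set")
  p1 <- colMeans(source1@alleles, na.rm = TRUE) / source1@ploidy
  p2 <- colMeans(source2@alleles, na.rm = TRUE) / source2@ploidy
  d <- p1 - p2
  d[is.nan(p1) | is.nan(p2)] <- NA_real_
  d
}

# Per-chromosome accumulators (value sum and pair count per bin) for one
# panel.  Genotype-dosage covariance is halved onto haplotype scale.
# Complete panels compute each chromosome's site covariance matrix with one
# BLAS crossproduct and bin the weighted products in a single O(sites^2)
# pass; panels with missing data (complete-case covariance per pair) go
# through the per-pair loop instead.
panelAccumulators <- function(panel, delta, bins) {
  chroms <- unique(panel@chrom)
  a <- panel@alleles
  if (anyNA(a) || nrow(a) < 4) {
    acc <- .ald_pair_accum(a * 1.0, panel@gpos,
                           match(panel@chrom, chroms), as.numeric(delta),
                           bins$dMin, bins$dMax, bins$binWidth, bins$nBins,
                           length(chroms), 1 / panel@ploidy)
    dimnames(acc$sum) <- dimnames(acc$count) <- list(NULL, chroms)
    return(acc)
  }
  n <- nrow(a)
  sum <- cnt <- matrix(0, bins$nBins, length(chroms),
                       dimnames = list(NULL, chroms))
  for (k in seq_along(chroms)) {
    sel <- panel@chrom == chroms[k]
    Xc <- a[, sel, drop = FALSE]
    Xc <- Xc - matrix(colMeans(Xc), n, ncol(Xc), byrow = TRUE)
    cv <- crossprod(Xc) / ((n - 1) * panel@ploidy)
    acc <- .cov_bin_accum(cv, panel@gpos[sel], as.numeric(delta)[sel],
                          bins$dMin, bins$dMax, bins$binWidth, bins$nBins)
    sum[, k] <- acc$sum
    cnt[, k] <- acc$count
  }
  list(sum = sum, count = cnt)
}

accToCurve <- function(acc, bins, drop = NULL, label = "full") {
  keep <- setdiff(colnames(acc$sum), drop)
  s <- rowSums(acc$sum[, keep, drop = FALSE])
  n <- rowSums(acc$count[, keep, drop = FALSE])
  ok <- n >= 1
  if (!any(ok)) stop("distance grid empty: no site pair in any bin")
  LDCurve(bins$mid[ok], s[ok] / n[ok], n[ok], label)
}

#' Weighted LD curve of one panel
#'
#' For each distance bin, the mean over same-chromosome site pairs (x, y)
#' in the bin of cov(x, y) * delta[x] * delta[y], where cov is the sample
#' covariance of allele values across haplotypes (unbiased denominator;
#' genotype-dosage covariance is halved onto haplotype scale).  Bins with no
#' pairs are dropped; pairs with fewer than 4 complete observations are
#' skipped.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param weights per-site weights from \code{\link{siteWeights}}.
#' @param bins a \code{\link{binSpec}}.
#' @param label curve label.
#' @return an \linkS4class{LDCurve}.
#' @export
weightedLDCurve <- function(panel, weights, bins = binSpec(), label = "full") {
  stopifnot(is(panel, "HaplotypePanel"), length(weights) == nSites(panel))
  accToCurve(panelAccumulators(panel, weights, bins), bins, label = label)
}

#' Combine panel curves into the background-corrected ALD curve
#'
#' z(d) = a0(d) - m1 * a1(d) - m2 * a2(d): subtracting the
#' proportion-weighted source curves removes the background-LD contribution
#' each source carries into the admixed population, leaving the
#' admixture-induced component.
#'
#' @param a0,a1,a2 weighted LD curves of the admixed panel and the two
#'   source panels, on a shared grid.
#' @param m1 source-1 admixture proportion; m2 = 1 - m1.
#' @return an \linkS4class{LDCurve} (pair counts taken from a0).
#' @export
aldCurve <- function(a0, a1, a2, m1) {
  stopifnot(is(a0, "LDCurve"), is(a1, "LDCurve"), is(a2, "LDCurve"),
            m1 > 0, m1 < 1)
  if (length(a0@d) != length(a1@d) || length(a0@d) != length(a2@d) ||
      any(a0@d != a1@d) || any(a0@d != a2@d))
    stop("curves are on different distance grids")
  LDCurve(a0@d, a0@z - m1 * a1@z - (1 - m1) * a2@z, a0@nPairs, a0@label)
}

#' Full + leave-one-chromosome-out ALD curve set from three panels
#'
#' Computes per-chromosome (sum, count) accumulators for the admixed and
#' both source panels, so the full-genome curve and every jackknife curve
#' are assembled by per-chromosome subtraction rather than recomputation.
#' Chromosomes contributing no within-chromosome pair are excluded from the
#' jackknife set with a warning.  Bins empty in the full curve or in any
#' jackknife are dropped from all curves so the set shares one grid.
#'
#' @param admixed,source1,source2 aligned \linkS4class{HaplotypePanel}s.
#' @param m1 source-1 admixture proportion.
#' @param bins a \code{\link{binSpec}}.
#' @return an \linkS4class{LDCurveSet}.
#' @export
curveSet <- function(admixed, source1, source2, m1, bins = binSpec()) {
  stopifnot(is(admixed, "HaplotypePanel"))
  if (nSites(admixed) != nSites(source1) ||
      any(admixed@chrom != source1@chrom) || any(admixed@gpos != source1@gpos))
    stop("admixed and source panels are not aligned on the same site set")
  chroms <- unique(admixed@chrom)
  if (length(chroms) < 2) stop("need at least 2 chromosomes for jackknives")
  delta <- siteWeights(source1, source2)
  acc0 <- panelAccumulators(admixed, delta, bins)
  acc1 <- panelAccumulators(source1, delta, bins)
  acc2 <- panelAccumulators(source2, delta, bins)

  empty <- chroms[colSums(acc0$count) == 0]
  if (length(empty)) {
    warning(sprintf("chromosome(s) %s have no within-chromosome pair; excluded from jackknife set",
                    paste(empty, collapse = ", ")))
    chroms <- setdiff(chroms, empty)
  }
  # bins populated in the full curve and every leave-one-out curve
  cnt <- acc0$count[, chroms, drop = FALSE]
  tot <- rowSums(cnt)
  keep <- tot - apply(cnt, 1, max) >= 1
  if (!any(keep)) stop("distance grid empty: no bin survives jackknifing")
  trim <- function(acc) list(sum = acc$sum[keep, , drop = FALSE],
                             count = acc$count[keep, , drop = FALSE])
  acc0 <- trim(acc0); acc1 <- trim(acc1); acc2 <- trim(acc2)
  binsK <- bins; binsK$mid <- bins$mid[keep]; binsK$nBins <- sum(keep)

  zfrom <- function(drop, label)
    aldCurve(accToCurve(acc0, binsK, drop, label),
             accToCurve(acc1, binsK, drop, label),
             accToCurve(acc2, binsK, drop, label), m1)
  full <- zfrom(NULL, "full")
  jack <- lapply(chroms, function(cc) zfrom(cc, paste0("drop_chrom:", cc)))
  names(jack) <- chroms
  LDCurveSet(full, jack, m1)
}
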