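# Independent oracles used across the suite.

# Naive all-pairs double loop for the binned weighted LD curve: complete-case
# sample covariance (unbiased denominator, dosages halved), pairs with < 4
# complete observations skipped, same-chromosome pairs only.
naiveWeightedLD <- function(panel, delta, bins) {
  a <- panel@alleles / panel@ploidy * panel@ploidy  # keep raw values
  p <- ncol(a)
  sums <- numeric(bins$nBins)
  cnts <- numeric(bins$nBins)
  for (x in seq_len(p - 1)) {
    if (is.na(delta[x])) next
    for (y in seq(x + 1, p)) {
      if (panel@chrom[x] != panel@chrom[y]) next
      if (is.na(delta[y])) next
      d <- abs(panel@gpos[y] - panel@gpos[x])
      if (d < bins$dMin || d > bins$dMax) next
      b <- min(floor((d - bins$dMin) / bins$binWidth) + 1, bins$nBins)
      ok <- !is.na(a[, x]) & !is.na(a[, y])
      if (sum(ok) < 4) next
      cv <- stats::cov(a[ok, x], a[ok, y]) / panel@ploidy
      sums[b] <- sums[b] + cv * delta[x] * delta[y]
      cnts[b] <- cnts[b] + 1
    }
  }
  keep <- cnts >= 1
  list(d = bins$mid[keep], z = sums[keep] / cnts[keep], n = cnts[keep])
}

# Exhaustive window search by brute force: every 1 <= E <= S <= J fitted
# with lm() on the curve built from the ledger-recursion coefficient vector.
exhaustiveWindowOracle <- function(z, d, model, J, m1 = 0.3) {
  best <- list(rss = Inf)
  for (S in seq_len(J)) for (E in seq_len(S)) {
    x <- modelCurve(coefficientVector(modelSpec(model, E, S, m1), J), d)
    fit <- stats::lm(z ~ x)
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best$rss - 1e-18) best <- list(E = E, S = S, rss = rss)
  }
  best
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranks of |d| (no ties, no zeros).
wilcoxEnumOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V <- as.numeric(signs %*% r)
  pLe <- mean(V <= v)
  pGe <- mean(V >= v)
  min(1, 2 * min(pLe, pGe))
}

# Holm-Bonferroni closed form.
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Theoretical curve-set builder: full + nJack curves all equal to the model
# curve plus iid Gaussian noise.
theoryCurveSet <- function(spec, bins = binSpec(0.005, 0.3, 0.001), J = 150L,
                           theta0 = 1e-4, theta1 = 5e-3, noiseSd = 0,
                           nJack = 10L) {
  base <- modelCurve(coefficientVector(spec, J), bins$mid, theta0, theta1)
  mk <- function(lab) LDCurve(bins$mid, base + rnorm(length(base), 0, noiseSd),
                              label = lab)
  LDCurveSet(mk("full"),
             lapply(seq_len(nJack), function(q) mk(paste0("drop_chrom:", q))),
             spec@m1)
}

# Proper leave-one-out curve set: N per-chromosome noisy curves averaged.
jackknifeCurveSet <- function(spec, bins, J, theta0, theta1, noiseSd, N) {
  base <- modelCurve(coefficientVector(spec, J), bins$mid, theta0, theta1)
  parts <- lapply(seq_len(N), function(q)
    base + rnorm(length(base), 0, noiseSd))
  avg <- function(idx) Reduce(`+`, parts[idx]) / length(idx)
  full <- LDCurve(bins$mid, avg(seq_len(N)), label = "full")
  jack <- lapply(seq_len(N), function(q)
    LDCurve(bins$mid, avg(setdiff(seq_len(N), q)),
            label = paste0("drop_chrom:", q)))
  LDCurveSet(full, jack, spec@m1)
}
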