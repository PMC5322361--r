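makePanel <- function(mat, nchrom = 1, label = "admixed", ploidy = 1L) {
  p <- ncol(mat)
  per <- p / nchrom
  HaplotypePanel(mat, rep(seq_len(nchrom), each = per),
                 rep(seq(0.01, 0.29, length.out = per), nchrom),
                 ploidy = ploidy, popLabel = label)
}

test_that("site weights are source allele-frequency differences", {
  s1 <- makePanel(rbind(c(1, 1, 0, 1), c(1, 1, 0, 0), c(1, 0, 0, 1),
                        c(1, 1, 0, 1), c(0, 1, 0, 1),
                        c(1, 1, 0, 1), c(1, 1, 0, 1), c(1, 1, 0, 1),
                        c(0, 0, 0, 0), c(1, 0, 0, 1)), label = "source1")
  s2 <- makePanel(matrix(0, 10, 4), label = "source2")
  w <- siteWeights(s1, s2)
  expect_equal(w, c(0.8, 0.7, 0, 0.8))
  # identical sources give identically zero weights
  expect_equal(siteWeights(s1, s1), rep(0, 4))
  # p1 = 0.7, p2 = 0.2 gives 0.5
  a <- makePanel(matrix(c(rep(1, 7), rep(0, 3)), 10, 1), label = "source1")
  b <- makePanel(matrix(c(rep(1, 2), rep(0, 8)), 10, 1), label = "source2")
  expect_equal(siteWeights(a, b), 0.5)
})

test_that("degenerate panels give zero curves", {
  # identical haplotypes: no variance anywhere
  pan <- makePanel(matrix(1, 8, 20))
  cv <- weightedLDCurve(pan, rep(1, 20), binSpec(0.005, 0.3, 0.05))
  expect_true(all(cv@z == 0))
  # balanced two-site haplotypes 00/01/10/11: zero covariance
  pan2 <- makePanel(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  cv2 <- weightedLDCurve(pan2, c(1, 1), binSpec(0.005, 0.3, 0.3))
  expect_equal(cv2@z, 0)
})

test_that("binned accumulation equals the naive all-pairs double loop", {
  set.seed(10)
  bins <- binSpec(0.005, 0.3, 0.01)
  for (ploidy in c(1L, 2L)) {
    mat <- matrix(rbinom(30 * 120, ploidy, 0.4), 30)
    pan <- makePanel(mat, nchrom = 2, ploidy = ploidy)
    delta <- runif(120, -1, 1)
    cv <- weightedLDCurve(pan, delta, bins)
    oracle <- naiveWeightedLD(pan, delta, bins)
    expect_equal(cv@d, oracle$d)
    expect_equal(cv@z, oracle$z, tolerance = 1e-12)
    expect_equal(cv@nPairs, oracle$n)
  }
  # missing data: complete-case covariance through the per-pair path
  mat <- matrix(rbinom(30 * 60, 1, 0.4), 30)
  mat[sample(length(mat), 150)] <- NA
  pan <- makePanel(mat)
  delta <- runif(60, -1, 1)
  cv <- weightedLDCurve(pan, delta, bins)
  oracle <- naiveWeightedLD(pan, delta, bins)
  expect_equal(cv@z, oracle$z, tolerance = 1e-12)
})

test_that("the ALD combination removes proportion-weighted source background", {
  d <- c(0.01, 0.05, 0.1)
  a1 <- LDCurve(d, c(1, 2, 3))
  a2 <- LDCurve(d, c(3, 2, 1))
  a0 <- LDCurve(d, 0.3 * a1@z + 0.7 * a2@z)
  expect_equal(aldCurve(a0, a1, a2, 0.3)@z, rep(0, 3))
  zero <- LDCurve(d, rep(0, 3))
  expect_equal(aldCurve(a0, zero, zero, 0.3)@z, a0@z)
  expect_error(aldCurve(a0, LDCurve(d + 0.01, a1@z), a2, 0.3), "grids")
})

test_that("jackknife curves come from per-chromosome subtraction", {
  set.seed(21)
  mat <- matrix(rbinom(40 * 90, 1, 0.5), 40)
  adm <- makePanel(mat, nchrom = 3)
  s1 <- makePanel(matrix(rbinom(40 * 90, 1, 0.7), 40), nchrom = 3, label = "source1")
  s2 <- makePanel(matrix(rbinom(40 * 90, 1, 0.3), 40), nchrom = 3, label = "source2")
  bins <- binSpec(0.005, 0.3, 0.02)
  cs <- curveSet(adm, s1, s2, 0.3, bins)
  expect_length(cs@jackknives, 3)

  # conservation: full bin sums equal the sum of per-chromosome sums
  delta <- siteWeights(s1, s2)
  acc <- camix:::panelAccumulators(adm, delta, bins)
  expect_equal(rowSums(acc$sum), rowSums(acc$sum[, 1, drop = FALSE]) +
                 rowSums(acc$sum[, 2, drop = FALSE]) +
                 rowSums(acc$sum[, 3, drop = FALSE]))

  # leave-one-out equals recomputation from scratch without that chromosome
  for (q in 1:3) {
    keep <- adm@chrom != as.character(q)
    sub <- function(p, lab) HaplotypePanel(p@alleles[, keep], p@chrom[keep],
                                           p@gpos[keep], 1L, lab)
    csq <- curveSet(sub(adm, "admixed"), sub(s1, "source1"),
                    sub(s2, "source2"), 0.3, bins)
    jk <- cs@jackknives[[as.character(q)]]
    shared <- match(csq@full@d, jk@d)
    expect_false(anyNA(shared))
    expect_equal(jk@z[shared], csq@full@z, tolerance = 1e-12)
  }

  # two identical chromosomes: each jackknife equals the full curve
  mat2 <- cbind(mat[, 1:30], mat[, 1:30])
  adm2 <- makePanel(mat2, nchrom = 2)
  s1b <- makePanel(cbind(s1@alleles[, 1:30], s1@alleles[, 1:30]), nchrom = 2,
                   label = "source1")
  s2b <- makePanel(cbind(s2@alleles[, 1:30], s2@alleles[, 1:30]), nchrom = 2,
                   label = "source2")
  cs2 <- curveSet(adm2, s1b, s2b, 0.3, bins)
  for (jc in cs2@jackknives)
    expect_equal(jc@z, cs2@full@z, tolerance = 1e-12)
})

test_that("relabeling the sources and flipping m1 leaves the ALD unchanged", {
  set.seed(31)
  sim <- simulatePanels(modelSpec("HI", 10, 10, 0.3), popSize = 400L,
                        chromLengths = rep(0.3, 3), nSample = 100L,
                        panelModel = sourcePanelModel(nSites = 200L),
                        nSourceHap = 60L)
  p <- sim$panels
  bins <- binSpec(0.005, 0.3, 0.01)
  z12 <- curveSet(p$admixed, p$source1, p$source2, 0.3, bins)
  z21 <- curveSet(p$admixed, p$source2, p$source1, 0.7, bins)
  expect_equal(z12@full@z, z21@full@z, tolerance = 1e-12)
})

test_that("an unadmixed population carries no ALD signal", {
  set.seed(41)
  # pure source-1 population: paint an unadmixed tract sample
  sch <- migrationSchedule(modelSpec("HI", 1, 1, 0.999))
  sch@alpha1[1] <- 1; sch@alpha2[1] <- 0   # all founders from source 1
  sim <- simulateTracts(new("SimConfig", schedule = sch, popSize = 400L,
                            chromLengths = rep(0.3, 4), nSample = 150L))
  expect_equal(ancestryProportion(sim), 1)
  pans <- paintHaplotypes(sim, sourcePanelModel(nSites = 300L), 100L,
                          method = "frequency")
  cs <- curveSet(pans$admixed, pans$source1, pans$source2, 0.5,
                 binSpec(0.005, 0.3, 0.01))
  z <- cs@full@z
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z)), 3 * se + 1e-12)
})

test_that("empty distance grids are rejected", {
  pan <- makePanel(matrix(rbinom(40, 1, 0.5), 10))  # 4 sites within 0.3 M
  expect_error(weightedLDCurve(pan, rep(1, 4), binSpec(0.40, 0.45, 0.01)),
               "distance grid empty")
})
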