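test_that("tracts tile every chromosome exactly and deterministically", {
  spec <- modelSpec("GA-I", 5, 30, 0.3)
  cfg <- simConfig(migrationSchedule(spec), popSize = 300L,
                   chromLengths = c(0.3, 0.2), nSample = 80L)
  set.seed(99)
  sim1 <- simulateTracts(cfg)
  set.seed(99)
  sim2 <- simulateTracts(cfg)
  expect_identical(sim1@tracts, sim2@tracts)

  tr <- sim1@tracts
  for (cc in 1:2) {
    sub <- tr[tr$chrom == cc, ]
    len <- tapply(sub$end - sub$start, sub$hap, sum)
    expect_equal(as.numeric(len), rep(cfg@chromLengths[cc], 80), tolerance = 1e-12)
    # starts chain onto previous ends within each haplotype
    for (h in unique(sub$hap)[1:5]) {
      hs <- sub[sub$hap == h, ]
      expect_equal(hs$start, c(0, utils::head(hs$end, -1)))
    }
  }
})

test_that("realized ancestry matches the schedule analytically", {
  set.seed(5)
  for (spec in list(modelSpec("HI", 20, 20, 0.3),
                    modelSpec("CGF1", 1, 40, 0.3),
                    modelSpec("GA-I", 10, 50, 0.3))) {
    cfg <- simConfig(migrationSchedule(spec), popSize = 5000L,
                     chromLengths = rep(0.3, 10), nSample = 2500L)
    sim <- simulateTracts(cfg)
    m <- ancestryProportion(sim)
    tol <- 3 * sqrt(0.3 * 0.7 / 2500) + 0.02   # sampling + drift allowance
    expect_lt(abs(m - 0.3), tol)
  }
})

test_that("tract boundaries accumulate at the pulse-model rate", {
  set.seed(6)
  sim <- simulateTracts(simConfig(migrationSchedule(modelSpec("HI", 20, 20, 0.3)),
                                  popSize = 5000L, chromLengths = rep(0.3, 10),
                                  nSample = 1000L))
  tr <- sim@tracts
  nSwitch <- nrow(tr) - 1000 * 10          # boundaries = tracts - hap*chrom
  density <- nSwitch / (1000 * 3)          # per Morgan over 3 M per hap
  expect_lt(abs(density - 2 * 0.3 * 0.7 * 20) / (2 * 0.3 * 0.7 * 20), 0.1)
})

test_that("ancestry LD of a pulse sample decays at the pulse rate", {
  set.seed(8)
  sim <- simulateTracts(simConfig(migrationSchedule(modelSpec("HI", 20, 20, 0.3)),
                                  popSize = 5000L, chromLengths = rep(0.3, 20),
                                  nSample = 800L))
  zc <- ancestryLDCurve(sim, binSpec(0.005, 0.3, 0.002), nLoci = 120L)
  A <- designMatrix(zc@d, 60L)
  nhat <- scanOnset(zc, A, "HI")@spec@gStart
  expect_true(nhat >= 18 && nhat <= 22)
  # log-linear decay over 0.01-0.2 M after removing the fitted offset
  fit <- scanOnset(zc, A, "HI")
  resid0 <- zc@z - fit@theta0
  ok <- zc@d >= 0.01 & zc@d <= 0.2 & resid0 > 0
  slope <- unname(coef(lm(log(resid0[ok]) ~ zc@d[ok]))[2])
  expect_lt(abs(-slope - 20), 5)
  # an unadmixed sample has no ancestry LD
  sch <- migrationSchedule(modelSpec("HI", 1, 1, 0.5))
  sch@alpha1[1] <- 1; sch@alpha2[1] <- 0
  pure <- simulateTracts(new("SimConfig", schedule = sch, popSize = 300L,
                             chromLengths = rep(0.3, 3), nSample = 120L))
  zp <- ancestryLDCurve(pure, binSpec(0.005, 0.3, 0.01), nLoci = 80L)
  expect_true(all(zp@z == 0))
})

test_that("painted panels reproduce the mixture allele frequencies", {
  set.seed(12)
  sim <- simulateTracts(simConfig(migrationSchedule(modelSpec("HI", 10, 10, 0.3)),
                                  popSize = 1000L, chromLengths = rep(0.3, 4),
                                  nSample = 400L))
  for (method in c("copy", "frequency")) {
    set.seed(13)
    pans <- paintHaplotypes(sim, sourcePanelModel(nSites = 500L), 200L,
                            method = method)
    p1 <- colMeans(pans$source1@alleles)
    p2 <- colMeans(pans$source2@alleles)
    m1 <- ancestryProportion(sim)
    mix <- m1 * p1 + (1 - m1) * p2
    freq <- colMeans(pans$admixed@alleles)
    expect_gt(cor(freq, mix), 0.95)
    expect_lt(abs(mean(freq - mix)), 0.01)
    expect_true(all(pans$admixed@alleles %in% c(0, 1)))
  }
  # determinism
  set.seed(14); a <- paintHaplotypes(sim, sourcePanelModel(nSites = 100L), 50L)
  set.seed(14); b <- paintHaplotypes(sim, sourcePanelModel(nSites = 100L), 50L)
  expect_identical(a$admixed@alleles, b$admixed@alleles)
})

test_that("vanishing source divergence erases the weighted-LD signal", {
  set.seed(15)
  sim <- simulateTracts(simConfig(migrationSchedule(modelSpec("HI", 10, 10, 0.3)),
                                  popSize = 600L, chromLengths = rep(0.3, 3),
                                  nSample = 200L))
  mkZ <- function(divergence) {
    set.seed(16)
    pans <- paintHaplotypes(sim, sourcePanelModel(nSites = 400L,
                                                  divergence = divergence), 150L)
    cs <- curveSet(pans$admixed, pans$source1, pans$source2, 0.3,
                   binSpec(0.005, 0.3, 0.01))
    mean(abs(cs@full@z))
  }
  expect_lt(mkZ(1e-3), mkZ(0.15) / 5)
})

test_that("curve fixtures round-trip through the fitting machinery", {
  dir <- tempfile("fix")
  spec <- modelSpec("HI", 30, 30, 0.3)
  p1 <- makeFixture("noiseless_curve", spec, dir, seed = 4)
  p2 <- makeFixture("noiseless_curve", spec, file.path(dir, "b"), seed = 4)
  expect_identical(readLines(p1), readLines(p2))
  cs <- readCurveSet(p1)
  A <- designMatrix(cs@full@d, 100L)
  expect_equal(scanOnset(cs@full, A, "HI")@spec@gStart, 30L)
  # panel fixtures satisfy panel invariants and reload cleanly
  pdir <- file.path(dir, "panels")
  paths <- makeFixture("panel_set", modelSpec("HI", 5, 5, 0.3), pdir, seed = 9)
  pans <- readPanels(paths["admixed"], paths["source1"], paths["source2"],
                     format = "plain_haps", map = paths["map"])
  expect_s4_class(pans$admixed, "HaplotypePanel")
  expect_equal(nSites(pans$admixed), 300)
})
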