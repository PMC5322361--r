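test_that("msE and quasi-F follow their definitions and thresholds", {
  expect_equal(msE(rep(0, 10)), 0)
  expect_equal(msE(c(3, 4)), 12.5)
  expect_error(msE(numeric(0)), "empty")
  expect_equal(MSE_THRESHOLD, 1e-5)
  expect_equal(QUASI_F_THRESHOLD, 1.5)

  e <- rnorm(50)
  expect_equal(quasiF(e, e), 1)
  expect_equal(quasiF(2 * e, e), 4)
  expect_warning(f <- quasiF(e, rep(0, 50)), "infinite")
  expect_identical(f, Inf)
})

test_that("pseudo values follow the Tukey jackknife construction", {
  LFull <- c(A = 1, B = 1)
  LDrop <- cbind(A = rep(1, 22), B = rep(0.9, 22))
  ps <- pseudoValues(LFull, LDrop)
  expect_equal(ps[, "A"], rep(1, 22))            # identity when drops equal full
  expect_equal(unname(ps[1, "B"]), 22 * 1 - 21 * 0.9)    # = 3.1
  expect_error(pseudoValues(LFull, LDrop[1, , drop = FALSE]), "N >= 2")
})

test_that("pseudo-value spread tracks replicate-to-replicate spread", {
  # proper leave-one-out curve sets: the jackknife variance of the pseudo
  # values should approximate the direct replicate variance of log(msE)
  bins <- binSpec(0.005, 0.3, 0.002)
  spec <- modelSpec("HI", 40, 40, 0.3)
  A <- designMatrix(bins$mid, 80L)
  N <- 10L
  set.seed(55)
  reps <- replicate(14, {
    cs <- jackknifeCurveSet(spec, bins, 80L, 1e-4, 5e-3, noiseSd = 3e-4, N = N)
    LFull <- log(scanOnset(cs@full, A, "HI")@msE)
    LDrop <- vapply(cs@jackknives, function(zc)
      log(scanOnset(zc, A, "HI")@msE), numeric(1))
    ps <- pseudoValues(c(HI = LFull), cbind(HI = LDrop))
    c(LFull, var(ps[, 1]) / N)
  })
  direct <- var(reps[1, ])
  jackEst <- mean(reps[2, ])
  expect_lt(abs(log(jackEst / direct)), log(2))
})

test_that("pairwise tests match exact enumeration and Holm's closed form", {
  set.seed(66)
  for (k in 1:5) {
    pseudo <- matrix(rnorm(8 * 3), 8, 3,
                     dimnames = list(NULL, c("HI", "GA-I", "CGF1-I")))
    adj <- pairwiseTests(pseudo)
    raw <- c(wilcoxEnumOracle(pseudo[, 1] - pseudo[, 2]),
             wilcoxEnumOracle(pseudo[, 1] - pseudo[, 3]),
             wilcoxEnumOracle(pseudo[, 2] - pseudo[, 3]))
    expected <- holmOracle(raw)
    expect_equal(adj["HI", "GA-I"], expected[1], tolerance = 1e-12)
    expect_equal(adj["HI", "CGF1-I"], expected[2], tolerance = 1e-12)
    expect_equal(adj["GA-I", "CGF1-I"], expected[3], tolerance = 1e-12)
    expect_equal(adj, t(adj))
    # Holm is monotone: adjusted never below raw
    expect_gte(adj["HI", "GA-I"], raw[1] - 1e-12)
    expect_gte(adj["HI", "CGF1-I"], raw[2] - 1e-12)
    expect_gte(adj["GA-I", "CGF1-I"], raw[3] - 1e-12)
  }
  # identical columns: all differences zero, p = 1
  same <- matrix(rep(rnorm(6), 3), 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(pairwiseTests(same) == 1, na.rm = TRUE))
})

test_that("the decision rule prefers HI unless significantly beaten", {
  models <- c("HI", "GA-I", "CGF1-I", "CGF2-I")
  mkP <- function(...) {
    v <- list(...)
    p <- matrix(NA_real_, 4, 4, dimnames = list(models, models))
    for (nm in names(v)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      p[pair[1], pair[2]] <- p[pair[2], pair[1]] <- v[[nm]]
    }
    p
  }
  # HI not significantly larger than the best: HI selected alone
  med <- c(HI = -9.8, "GA-I" = -10, "CGF1-I" = -9.5, "CGF2-I" = -9.4)
  sel <- selectBest(med, mkP("HI:GA-I" = 0.3, "HI:CGF1-I" = 0.2,
                             "HI:CGF2-I" = 0.9, "GA-I:CGF1-I" = 0.1,
                             "GA-I:CGF2-I" = 0.4, "CGF1-I:CGF2-I" = 0.8))
  expect_identical(sel$bestSet, "HI")
  expect_false(sel$undetermined)
  # HI significantly larger: best plus its non-beaten peers
  sel2 <- selectBest(med, mkP("HI:GA-I" = 0.01, "HI:CGF1-I" = 0.01,
                              "HI:CGF2-I" = 0.01, "GA-I:CGF1-I" = 0.3,
                              "GA-I:CGF2-I" = 0.01, "CGF1-I:CGF2-I" = 0.9))
  expect_setequal(sel2$bestSet, c("GA-I", "CGF1-I"))
  expect_true(sel2$undetermined)
  # dominance: every adjusted p small, HI beaten -> singleton
  med3 <- c(HI = -9, "GA-I" = -12, "CGF1-I" = -9.5, "CGF2-I" = -9.4)
  allSmall <- mkP("HI:GA-I" = 0.01, "HI:CGF1-I" = 0.01, "HI:CGF2-I" = 0.01,
                  "GA-I:CGF1-I" = 0.01, "GA-I:CGF2-I" = 0.01,
                  "CGF1-I:CGF2-I" = 0.01)
  sel3 <- selectBest(med3, allSmall)
  expect_identical(sel3$bestSet, "GA-I")
  # significance requires the median direction too
  med4 <- c(HI = -10.5, "GA-I" = -10.4, "CGF1-I" = -9, "CGF2-I" = -9)
  sel4 <- selectBest(med4, allSmall)
  expect_identical(sel4$bestSet, "HI")  # HI's median is below the best's
})

test_that("time intervals summarize by majority coverage and HI by the mean", {
  mk <- function(model, E, S) new("FitResult", spec = modelSpec(model, E, S, 0.3),
                                  theta0 = 0, theta1 = 1, rss = 0, msE = 0,
                                  quasiF = NA_real_, degenerate = FALSE)
  same <- lapply(1:8, function(i) mk("GA-I", 2, 8))
  expect_equal(summarizeIntervals(same)[c("gEnd", "gStart")],
               list(gEnd = 2, gStart = 8))
  hi <- lapply(c(5, 5, 6), function(n) mk("HI", n, n))
  expect_equal(summarizeIntervals(hi)$gStart, 5)

  set.seed(77)
  E <- sample(1:10, 22, replace = TRUE)
  S <- E + sample(5:20, 22, replace = TRUE)
  fits <- Map(function(e, s) mk("CGF1-I", e, s), E, S)
  got <- summarizeIntervals(fits)
  cover <- vapply(seq_len(max(S)), function(g) sum(E <= g & g <= S), numeric(1))
  maj <- which(cover > 11)
  expect_equal(got$gEnd, min(maj))
  expect_equal(got$gStart, max(maj))
})

test_that("selection collapses to full-curve comparison when jackknives agree", {
  set.seed(88)
  bins <- binSpec(0.005, 0.3, 0.002)
  spec <- modelSpec("HI", 30, 30, 0.3)
  cs <- theoryCurveSet(spec, bins, J = 80L, noiseSd = 2e-4, nJack = 6L)
  # make every jackknife identical to the full curve
  cs@jackknives <- lapply(seq_along(cs@jackknives), function(q) {
    jc <- cs@full; jc@label <- paste0("drop_chrom:", q); jc
  })
  rep <- selectModels(cs, c("HI", "GA-I", "CGF1-I", "CGF2-I"), J = 80L)
  expect_true(all(rep@adjP == 1, na.rm = TRUE))
  expect_identical(bestModels(rep), "HI")
})

test_that("selection outcomes classify correctly against the truth", {
  expect_equal(classifySelection(c("CGF1", "CGF2"), "CGF1"), "correct")
  expect_equal(classifySelection("GA-I", "GA"), "correct")
  expect_equal(classifySelection("CGF2-I", "CGF1"), "correct")
  expect_equal(classifySelection("HI", "GA-I"), "wrong")
  expect_equal(classifySelection("GA", "GA-I"), "wrong")
  expect_equal(classifySelection(c("HI", "GA-I"), "HI"), "undetermined")
  expect_equal(classifySelection(c("GA-I", "CGF1-I"), "CGF1-I"), "undetermined")
  expect_equal(classifySelection("HI", "HI"), "correct")
})
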