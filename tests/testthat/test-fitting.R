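dGrid <- binSpec(0.005, 0.3, 0.002)$mid

test_that("the design matrix is the exponential-decay basis", {
  A <- designMatrix(0.1, J = 2L)
  expect_equal(A@A[1, ], c(exp(-0.1), exp(-0.2)))
  B <- designMatrix(dGrid, J = 30L)
  expect_true(all(apply(B@A, 1, diff) < 0))       # decreasing along rows
  expect_equal(B@A[, 7], exp(-7 * dGrid))         # column l at d = column 1 at l d
  expect_true(all(B@A > 0 & B@A < 1))
})

test_that("theta is recovered exactly from a realizable curve", {
  A <- designMatrix(dGrid, J = 60L)
  C <- coefficientVector(modelSpec("GA-I", 10, 40, 0.3), J = 60L)
  z <- 2 * as.numeric(A@A %*% C@coef) + 0.5
  fit <- fitTheta(LDCurve(dGrid, z), A, C)
  expect_equal(fit$theta0, 0.5, tolerance = 1e-10)
  expect_equal(fit$theta1, 2, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  # constant curve: offset-only fit with zero residual
  fitc <- fitTheta(LDCurve(dGrid, rep(1.5, length(dGrid))), A, C)
  expect_equal(fitc$theta1, 0)
  expect_lt(fitc$rss, 1e-20)
})

test_that("OLS matches an independent solver on a noisy curve", {
  set.seed(1)
  A <- designMatrix(dGrid[1:100], J = 60L)
  C <- coefficientVector(modelSpec("CGF1-I", 5, 30, 0.3), J = 60L)
  x <- as.numeric(A@A %*% C@coef)
  z <- x + rnorm(100)
  fit <- fitTheta(z, A, C)
  ref <- lm(z ~ x)
  expect_equal(fit$theta0, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(fit$theta1, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(fit$rss, sum(residuals(ref)^2), tolerance = 1e-8)
})

test_that("onset scans recover noiseless curves exactly", {
  A <- designMatrix(dGrid, J = 100L)
  cases <- list(list("HI", 30L), list("GA", 50L), list("CGF1", 50L),
                list("CGF2", 40L))
  for (cs in cases) {
    spec <- if (cs[[1]] == "HI") modelSpec("HI", cs[[2]], cs[[2]], 0.3)
            else modelSpec(cs[[1]], 1L, cs[[2]], 0.3)
    z <- modelCurve(coefficientVector(spec, 100L), dGrid, 1e-4, 5e-3)
    fit <- scanOnset(LDCurve(dGrid, z), A, cs[[1]])
    expect_equal(fit@spec@gStart, cs[[2]])
    expect_equal(fit@theta0, 1e-4, tolerance = 1e-8)
    expect_lt(fit@rss, 1e-15)
    # the objective at the truth strictly dominates every other onset
    G <- camix:::onsetBank(cs[[1]], A, 0.3)
    rssAll <- camix:::olsMany(z, G)$rss
    expect_true(all(rssAll[-cs[[2]]] > rssAll[cs[[2]]] + 1e-12))
  }
})

test_that("a single-candidate scan returns that candidate", {
  A1 <- designMatrix(dGrid, J = 1L)
  z <- rnorm(length(dGrid))
  expect_equal(scanOnset(LDCurve(dGrid, z), A1, "HI")@spec@gStart, 1L)
})

test_that("fitting HI to a continuous-admixture curve lands inside the window", {
  A <- designMatrix(dGrid, J = 100L)
  z <- modelCurve(coefficientVector(modelSpec("GA", 1, 50, 0.3), 100L),
                  dGrid, 1e-4, 5e-3)
  fit <- scanOnset(LDCurve(dGrid, z), A, "HI")
  expect_gt(fit@spec@gStart, 1L)
  expect_lt(fit@spec@gStart, 50L)
})

test_that("interval search equals exhaustive search on noiseless curves", {
  J <- 60L
  A <- designMatrix(dGrid, J)
  for (cs in list(c("GA-I", 10, 40), c("CGF1-I", 20, 50), c("CGF2-I", 5, 25))) {
    spec <- modelSpec(cs[1], as.integer(cs[2]), as.integer(cs[3]), 0.3)
    z <- modelCurve(coefficientVector(spec, J), dGrid, 1e-4, 5e-3)
    fit <- intervalSearch(LDCurve(dGrid, z), A, cs[1])
    oracle <- exhaustiveWindowOracle(z, dGrid, cs[1], J)
    expect_equal(fit@spec@gEnd, oracle$E)
    expect_equal(fit@spec@gStart, oracle$S)
    expect_equal(fit@spec@gEnd, as.integer(cs[2]))
    expect_equal(fit@spec@gStart, as.integer(cs[3]))
    expect_lte(fit@rss, oracle$rss + 1e-12)
  }
})

test_that("a pulse curve searched with an interval model concentrates on the pulse", {
  J <- 60L
  A <- designMatrix(dGrid, J)
  z <- modelCurve(coefficientVector(modelSpec("HI", 25, 25, 0.3), J),
                  dGrid, 1e-4, 5e-3)
  fit <- intervalSearch(LDCurve(dGrid, z), A, "GA-I")
  oracle <- exhaustiveWindowOracle(z, dGrid, "GA-I", J)
  expect_lte(fit@rss, oracle$rss + 1e-12)
  expect_true(fit@spec@gEnd <= 25 && 25 <= fit@spec@gStart)
})

test_that("a flat curve terminates at the full window with zero scale", {
  A <- designMatrix(dGrid, J = 40L)
  flat <- LDCurve(dGrid, rep(2e-4, length(dGrid)))
  for (method in c("exhaustive", "greedy")) {
    fit <- intervalSearch(flat, A, "GA-I", method = method)
    expect_equal(unname(timeWindow(fit)), c(1L, 40L))
    expect_equal(fit@theta1, 0)
  }
})

test_that("greedy descent matches the exhaustive optimum on smooth surfaces", {
  J <- 60L
  A <- designMatrix(dGrid, J)
  z <- modelCurve(coefficientVector(modelSpec("CGF1-I", 20, 50, 0.3), J),
                  dGrid, 1e-4, 5e-3)
  g <- intervalSearch(LDCurve(dGrid, z), A, "CGF1-I", method = "greedy")
  e <- intervalSearch(LDCurve(dGrid, z), A, "CGF1-I", method = "exhaustive")
  expect_equal(timeWindow(g), timeWindow(e))
})

test_that("the reference fit reproduces realizable exponential mixtures", {
  A <- designMatrix(dGrid, J = 100L)
  z <- 3e-3 * exp(-5 * dGrid) + 1e-3 * exp(-60 * dGrid) + 2e-4
  ref <- referenceFit(LDCurve(dGrid, z), A)
  expect_lt(ref@rss, 1e-16)
  expect_true(all(ref@alpha >= 0))
  set.seed(2)
  zn <- z + rnorm(length(z), 0, 2e-4)
  refn <- referenceFit(LDCurve(dGrid, zn), A)
  expect_true(all(refn@alpha >= 0))
})

test_that("the reference fit is at least as good as every single-model fit", {
  set.seed(3)
  A <- designMatrix(dGrid, J = 80L)
  for (k in 1:3) {
    spec <- modelSpec("GA-I", sample(5:15, 1), sample(30:60, 1), 0.3)
    z <- modelCurve(coefficientVector(spec, 80L), dGrid, 1e-4, 5e-3) +
      rnorm(length(dGrid), 0, 3e-4)
    zc <- LDCurve(dGrid, z)
    ref <- referenceFit(zc, A)
    for (m in c("HI", "GA", "CGF1", "CGF2", "GA-I"))
      expect_lte(ref@rss, fitModel(zc, A, m)@rss + 1e-12)
  }
})

test_that("onset estimates are noise-robust for a recent pulse", {
  J <- 100L
  A <- designMatrix(dGrid, J)
  base <- modelCurve(coefficientVector(modelSpec("HI", 50, 50, 0.3), J),
                     dGrid, 1e-4, 5e-3)
  sd <- 0.05 * diff(range(base))
  set.seed(11)
  hits <- 0L
  for (k in 1:100) {
    z <- base + rnorm(length(base), 0, sd)
    n <- scanOnset(LDCurve(dGrid, z), A, "HI")@spec@gStart
    if (n >= 45 && n <= 55) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
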