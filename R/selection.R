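#' Mean squared residual of a fit
#'
#' msE = mean(e_i^2); values above 1e-5 flag low data quality.
#'
#' @param residuals residual vector of a model fit.
#' @return the mean squared residual.
#' @export
msE <- function(residuals) {
  if (length(residuals) == 0) stop("empty residual vector")
  mean(residuals^2)
}

#' msE low-quality threshold (1e-5)
#' @export
MSE_THRESHOLD <- 1e-5

#' quasi-F model-rejection threshold (1.5)
#' @export
QUASI_F_THRESHOLD <- 1.5

#' Quasi-F diagnostic
#'
#' The ratio of the core-model fit's residual sum of squares to that of the
#' flexible exponential-mixture reference fit on the same curve.  A value
#' near 1 means the core model fits as well as the de-noised reference;
#' values above 1.5 flag model rejection.
#'
#' @param modelResiduals residuals of the core-model fit.
#' @param referenceResiduals residuals of the reference fit.
#' @return the quasi-F ratio (+Inf, with a warning, when the reference
#'   residuals are exactly zero but the model residuals are not).
#' @export
quasiF <- function(modelResiduals, referenceResiduals) {
  num <- sum(modelResiduals^2)
  den <- sum(referenceResiduals^2)
  if (den == 0) {
    if (num == 0) return(1)
    warning("reference fit is exact; quasi-F is infinite")
    return(Inf)
  }
  num / den
}

#' Tukey jackknife pseudo values of log(msE)
#'
#' pseudo[q, M] = N * L_full[M] - (N - 1) * L_drop[q, M], where L is
#' log(msE) from the full-genome fit and from the fit with chromosome q
#' left out; the pseudo values are treated as approximately independent
#' replicates in the pairwise tests.
#'
#' @param LFull named per-model vector of full-curve log(msE).
#' @param LDrop N x M matrix of per-jackknife, per-model log(msE).
#' @return N x M pseudo-value matrix.
#' @export
pseudoValues <- function(LFull, LDrop) {
  LDrop <- as.matrix(LDrop)
  N <- nrow(LDrop)
  if (N < 2) stop("need N >= 2 jackknife fits")
  if (length(LFull) != ncol(LDrop)) stop("LFull/LDrop model mismatch")
  out <- N * matrix(LFull, N, length(LFull), byrow = TRUE) - (N - 1) * LDrop
  colnames(out) <- names(LFull)
  out
}

logMsE <- function(m) {
  if (m <= 0) {
    warning("msE of 0; substituting machine epsilon before log")
    m <- .Machine$double.eps
  }
  log(m)
}

#' Pairwise Wilcoxon signed-rank tests on pseudo values
#'
#' Two-sided Wilcoxon signed-rank on the paired differences (paired by
#' jackknife index q) for every model pair, exact distribution when there
#' are at most 25 informative pairs and no ties, normal approximation
#' otherwise; zero differences are dropped (p = 1 if all differences are
#' zero).  P-values are Holm-Bonferroni adjusted over the set of pairs.
#'
#' @param pseudo N x M pseudo-value matrix with model column names.
#' @return symmetric M x M matrix of adjusted p-values (NA diagonal).
#' @export
pairwiseTests <- function(pseudo) {
  pseudo <- as.matrix(pseudo)
  M <- ncol(pseudo)
  if (M < 2) stop("need at least 2 models")
  models <- colnames(pseudo)
  pairs <- utils::combn(M, 2)
  raw <- apply(pairs, 2, function(ij) {
    d <- pseudo[, ij[1]] - pseudo[, ij[2]]
    d <- d[d != 0]
    # no informative pairs, or a constant difference (the jackknife units
    # carry no independent replication): no evidence either way
    if (length(d) == 0 || stats::sd(d) == 0) return(1)
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    suppressWarnings(
      stats::wilcox.test(d, exact = exact, correct = !exact)$p.value)
  })
  adj <- stats::p.adjust(raw, method = "holm")
  out <- matrix(NA_real_, M, M, dimnames = list(models, models))
  for (k in seq_len(ncol(pairs)))
    out[pairs[1, k], pairs[2, k]] <- out[pairs[2, k], pairs[1, k]] <- adj[k]
  out
}

#' Best-fit model decision rule
#'
#' The best model is the one with the smallest sample median of pseudo
#' log(msE).  A model is "significantly larger than the best" when its
#' Holm-adjusted p-value against the best model is below `alpha` AND its
#' median exceeds the best model's.  If HI is not significantly larger than
#' the best model, HI alone is selected (the simplest model wins ties);
#' otherwise every model not significantly larger than the best is selected
#' (including the best model itself).  More than one selected model means
#' the decision is undetermined.
#'
#' @param medians named per-model medians of pseudo log(msE) (or the pseudo
#'   matrix itself, from which column medians are taken).
#' @param adjP symmetric adjusted p-value matrix from
#'   \code{\link{pairwiseTests}}.
#' @param alpha significance level (default 0.05).
#' @return list with `bestSet` (character) and `undetermined` (logical).
#' @export
selectBest <- function(medians, adjP, alpha = 0.05) {
  if (is.matrix(medians)) medians <- apply(medians, 2, stats::median)
  models <- names(medians)
  stopifnot(!is.null(models), all(models %in% rownames(adjP)))
  best <- models[which.min(medians)]
  sigLarger <- vapply(models, function(M) {
    if (M == best) return(FALSE)
    p <- adjP[M, best]
    !is.na(p) && p < alpha && medians[M] > medians[best]
  }, logical(1))
  bestSet <- if ("HI" %in% models && !sigLarger["HI"]) "HI"
             else models[!sigLarger]
  list(bestSet = unname(bestSet), undetermined = length(bestSet) > 1)
}

#' Summarize fitted time intervals over jackknives
#'
#' Continuous models: the set of generations covered by more than half of
#' the jackknife intervals, reported as its [min, max] (falling back to the
#' full-curve interval, flagged, when no generation reaches majority
#' coverage).  HI: the nearest integer to the mean of the jackknife point
#' estimates.
#'
#' @param fits list of per-jackknife \linkS4class{FitResult}s for one model.
#' @param fullFit the full-curve \linkS4class{FitResult} (fallback).
#' @return list with `gEnd`, `gStart` and `majorityEmpty` flag.
#' @export
summarizeIntervals <- function(fits, fullFit = NULL) {
  stopifnot(length(fits) >= 1)
  model <- fits[[1]]@spec@model
  if (model == "HI") {
    n <- round(mean(vapply(fits, function(f) f@spec@gStart, numeric(1))))
    return(list(gEnd = n, gStart = n, majorityEmpty = FALSE))
  }
  ends <- vapply(fits, function(f) f@spec@gEnd, numeric(1))
  starts <- vapply(fits, function(f) f@spec@gStart, numeric(1))
  gens <- seq_len(max(starts))
  cover <- vapply(gens, function(g) sum(ends <= g & g <= starts), numeric(1))
  maj <- gens[cover > length(fits) / 2]
  if (length(maj) == 0) {
    if (is.null(fullFit)) fullFit <- fits[[1]]
    return(list(gEnd = fullFit@spec@gEnd, gStart = fullFit@spec@gStart,
                majorityEmpty = TRUE))
  }
  list(gEnd = min(maj), gStart = max(maj), majorityEmpty = FALSE)
}

#' Fit core models to a curve set and select the best-fit model(s)
#'
#' The full pipeline downstream of the ALD curves: every core model is
#' fitted (with its own time search) to the full-genome curve and to each
#' of the N leave-one-chromosome-out curves; Tukey pseudo log(msE) values
#' feed pairwise Wilcoxon signed-rank tests with Holm adjustment and the
#' best-fit decision rule; time intervals are summarized over jackknives;
#' msE and quasi-F (against the flexible exponential-mixture reference fit
#' of the full curve) diagnostics are reported with their thresholds.
#'
#' @param curves an \linkS4class{LDCurveSet}.
#' @param models core model set, e.g. c("HI","GA","CGF1","CGF2") or
#'   c("HI","GA-I","CGF1-I","CGF2-I").
#' @param J basis size / onset upper bound in generations (default 500).
#' @param alpha significance level for the pairwise tests.
#' @return a \linkS4class{SelectionReport}.
#' @export
selectModels <- function(curves, models = c("HI", "GA-I", "CGF1-I", "CGF2-I"),
                         J = 500L, alpha = 0.05) {
  stopifnot(is(curves, "LDCurveSet"), length(models) >= 1,
            all(models %in% MODEL_NAMES))
  m1 <- curves@m1
  A <- designMatrix(curves@full@d, J)
  N <- length(curves@jackknives)

  fullFits <- lapply(models, function(M) fitModel(curves@full, A, M, m1))
  names(fullFits) <- models
  jackFits <- lapply(models, function(M)
    lapply(curves@jackknives, function(zc) fitModel(zc, A, M, m1)))
  names(jackFits) <- models

  ref <- referenceFit(curves@full, A)
  refRes <- curves@full@z - ref@fitted
  for (M in models) {
    f <- fullFits[[M]]
    res <- residualsOf(curves@full, A, f)
    f@quasiF <- quasiF(res, refRes)
    fullFits[[M]] <- f
  }

  LFull <- vapply(fullFits, function(f) logMsE(f@msE), numeric(1))
  LDrop <- vapply(jackFits, function(fl)
    vapply(fl, function(f) logMsE(f@msE), numeric(1)),
    numeric(N))
  pseudo <- pseudoValues(LFull, LDrop)
  if (length(models) == 1) {
    adjP <- matrix(NA_real_, 1, 1, dimnames = list(models, models))
    sel <- list(bestSet = models, undetermined = FALSE)
  } else {
    adjP <- pairwiseTests(pseudo)
    sel <- selectBest(pseudo, adjP, alpha)
  }

  ts <- lapply(models, function(M) summarizeIntervals(jackFits[[M]], fullFits[[M]]))
  diag <- data.frame(
    model = models,
    gEnd = vapply(ts, `[[`, numeric(1), "gEnd"),
    gStart = vapply(ts, `[[`, numeric(1), "gStart"),
    theta0 = vapply(fullFits, function(f) f@theta0, numeric(1)),
    theta1 = vapply(fullFits, function(f) f@theta1, numeric(1)),
    msE = vapply(fullFits, function(f) f@msE, numeric(1)),
    quasiF = vapply(fullFits, function(f) f@quasiF, numeric(1)),
    lowQuality = vapply(fullFits, function(f) f@msE > MSE_THRESHOLD, logical(1)),
    rejected = vapply(fullFits, function(f) f@quasiF > QUASI_F_THRESHOLD, logical(1)),
    nonPhysical = vapply(fullFits, function(f) f@theta1 < 0, logical(1)),
    best = models %in% sel$bestSet,
    row.names = NULL)

  new("SelectionReport", pseudo = pseudo, adjP = adjP, bestSet = sel$bestSet,
      undetermined = sel$undetermined, timeSummary = diag[, 1:3],
      diagnostics = diag, fits = fullFits, alpha = alpha)
}

# residuals of a fitted core model on a curve
residualsOf <- function(Z, A, fit) {
  s <- fit@spec
  x <- as.numeric(A@A %*% windowCoefficients(s@model, s@gEnd, s@gStart, s@m1,
                                             ncol(A@A)))
  Z@z - (fit@theta0 + fit@theta1 * x)
}

#' Classify a selection outcome against the true model
#'
#' Maps models to classes (CGF1/CGF2 -> "CGF", CGF1-I/CGF2-I -> "CGF-I")
#' and classifies the best-fit set as "correct" (the single matched class
#' is the truth), "undetermined" (the truth is among several selected
#' classes) or "wrong" (the truth is not selected).  An isolation-model
#' class also matches its non-interval counterpart as truth (GA-I covers
#' GA, CGF-I covers CGF), since the latter is the boundary case of the
#' former.
#'
#' @param bestSet selected model names.
#' @param trueModel the simulated model name.
#' @return "correct", "undetermined" or "wrong".
#' @export
classifySelection <- function(bestSet, trueModel) {
  cls <- function(m) c(HI = "HI", GA = "GA", CGF1 = "CGF", CGF2 = "CGF",
                       "GA-I" = "GA-I", "CGF1-I" = "CGF-I",
                       "CGF2-I" = "CGF-I")[m]
  matches <- function(core, truth)
    core == truth || (core == "GA-I" && truth == "GA") ||
      (core == "CGF-I" && truth == "CGF")
  truth <- unname(cls(trueModel))
  classes <- unique(unname(cls(bestSet)))
  hit <- vapply(classes, matches, logical(1), truth = truth)
  if (!any(hit)) "wrong"
  else if (length(classes) == 1) "correct"
  else "undetermined"
}
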