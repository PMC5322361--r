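#' Exponential-decay design matrix
#'
#' A[i, l] = exp(-l * d_i) for l = 1..J: the basis in which every admixture
#' model's ALD curve is linear.
#'
#' @param d distance grid, Morgans, all > 0.
#' @param J basis size (default 500, a generous upper bound for the
#'   admixture onset in generations).
#' @return a \linkS4class{DesignMatrix}.
#' @examples
#' designMatrix(c(0.01, 0.05, 0.1), J = 20)
#' @export
designMatrix <- function(d, J = 500L) {
  d <- as.numeric(d)
  stopifnot(all(d > 0), J >= 1)
  new("DesignMatrix", A = exp(-outer(d, seq_len(as.integer(J)))), d = d)
}

asCurveValues <- function(Z) {
  if (is(Z, "LDCurve")) Z@z else as.numeric(Z)
}

checkGrid <- function(Z, A) {
  if (is(Z, "LDCurve") && (length(Z@d) != length(A@d) ||
                           any(abs(Z@d - A@d) > 1e-12)))
    stop("curve and design matrix are on different distance grids")
}

# OLS of z on [1, x]; returns theta0, theta1, rss, degenerate flag.
# Closed form via centered sums; x numerically constant -> offset-only fit.
olsLine <- function(z, x) {
  I <- length(z)
  mz <- mean(z); mx <- mean(x)
  zc <- z - mz; xc <- x - mx
  Sxx <- sum(xc^2); Szz <- sum(zc^2)
  if (Sxx <= 1e-30 * I * max(mx^2, 1)) {
    return(list(theta0 = mz, theta1 = 0, rss = Szz, degenerate = TRUE))
  }
  Sxz <- sum(xc * zc)
  t1 <- Sxz / Sxx
  list(theta0 = mz - t1 * mx, theta1 = t1, rss = max(Szz - Sxz^2 / Sxx, 0),
       degenerate = FALSE)
}

#' Fit (theta0, theta1) for a fixed coefficient vector
#'
#' Ordinary least squares of the observed curve on the regressors
#' [1, A %*% C].
#'
#' @param Z an \linkS4class{LDCurve} (or numeric values on A's grid).
#' @param A a \linkS4class{DesignMatrix} on the curve's grid.
#' @param C a \linkS4class{CoefficientVector} with length ncol(A).
#' @return list with theta0, theta1, rss and a degenerate flag (TRUE when
#'   the model curve is numerically constant and theta1 is forced to 0).
#' @export
fitTheta <- function(Z, A, C) {
  stopifnot(is(A, "DesignMatrix"))
  checkGrid(Z, A)
  cvec <- if (is(C, "CoefficientVector")) C@coef else as.numeric(C)
  stopifnot(length(cvec) == ncol(A@A))
  olsLine(asCurveValues(Z), as.numeric(A@A %*% cvec))
}

# Vectorized OLS over many candidate model curves (columns of G).
# Returns rss vector plus theta0/theta1 vectors.
olsMany <- function(z, G) {
  I <- length(z)
  mz <- mean(z); zc <- z - mz
  Szz <- sum(zc^2)
  mx <- colMeans(G)
  Sxx <- colSums(G^2) - I * mx^2
  Sxz <- as.numeric(crossprod(G, zc))
  bad <- Sxx <= 1e-30 * I * pmax(mx^2, 1)
  t1 <- ifelse(bad, 0, Sxz / Sxx)
  rss <- pmax(ifelse(bad, Szz, Szz - Sxz^2 / Sxx), 0)
  list(theta0 = mz - t1 * mx, theta1 = t1, rss = rss, degenerate = bad)
}

# Session cache for per-(model, J, m1, grid) banks of candidate curves.
.camixCache <- new.env(parent = emptyenv())

bankKey <- function(model, A, m1)
  paste(model, ncol(A@A), m1, length(A@d), A@d[1], A@d[length(A@d)], sep = "|")

# G[, n] = A %*% C_model(window (n,n) for HI, (1,n) otherwise), n = 1..J.
onsetBank <- function(model, A, m1) {
  key <- bankKey(model, A, m1)
  if (!is.null(.camixCache[[key]])) return(.camixCache[[key]])
  J <- ncol(A@A)
  G <- if (model == "HI") {
    A@A * (m1 * (1 - m1))   # same scaling as windowCoefficients
  } else {
    Cmat <- vapply(seq_len(J), function(n)
      windowCoefficients(model, 1L, n, m1, J), numeric(J))
    A@A %*% Cmat
  }
  .camixCache[[key]] <- G
  G
}

fitResultFrom <- function(model, E, S, m1, fit, I)
  new("FitResult",
      spec = modelSpec(model, E, S, m1),
      theta0 = fit$theta0, theta1 = fit$theta1, rss = fit$rss,
      msE = fit$rss / I, quasiF = NA_real_,
      degenerate = isTRUE(fit$degenerate))

#' Scan the admixture onset for a non-interval core model
#'
#' Builds the model coefficient vector for every onset n = 1..J, fits
#' (theta0, theta1) by OLS for each, and returns the onset minimizing the
#' residual sum of squares (ties broken toward smaller n).
#'
#' @param Z an \linkS4class{LDCurve}.
#' @param A a \linkS4class{DesignMatrix} on the curve's grid.
#' @param model one of "HI", "GA", "CGF1", "CGF2".
#' @param m1 source-1 admixture proportion (GA/CGF shapes depend on it).
#' @return a \linkS4class{FitResult}.
#' @export
scanOnset <- function(Z, A, model = c("HI", "GA", "CGF1", "CGF2"), m1 = 0.3) {
  model <- match.arg(model)
  checkGrid(Z, A)
  z <- asCurveValues(Z)
  G <- onsetBank(model, A, m1)
  ols <- olsMany(z, G)
  n <- which.min(ols$rss)
  fitResultFrom(model, if (model == "HI") n else 1L, n, m1,
                lapply(ols, `[`, n), length(z))
}

# All admixture windows 1 <= E <= S <= J, widest first so the degenerate
# (flat-curve) tie resolves to (1, J), then by E ascending.
windowIndex <- function(J) {
  do.call(rbind, lapply(seq(J - 1, 0), function(width)
    cbind(E = seq_len(J - width), S = seq_len(J - width) + width)))
}

# Candidate-curve bank for exhaustive window search: G[, k] = A %*% C(E_k,
# S_k).  Cached per (model, J, m1, grid); the cache holds a handful of
# banks and evicts the oldest.
windowBank <- function(model, A, m1) {
  key <- paste("win", bankKey(model, A, m1))
  got <- .camixCache[[key]]
  if (!is.null(got)) return(got)
  J <- ncol(A@A)
  idx <- windowIndex(J)
  Cmat <- matrix(0, J, nrow(idx))
  for (k in seq_len(nrow(idx)))
    Cmat[, k] <- windowCoefficients(model, idx[k, 1], idx[k, 2], m1, J)
  bank <- list(idx = idx, G = A@A %*% Cmat)
  keys <- ls(.camixCache, pattern = "^win ")
  if (length(keys) >= 8) rm(list = keys[1], envir = .camixCache)
  .camixCache[[key]] <- bank
  bank
}

#' Admixture-window search for isolation models
#'
#' Fits the admixture window (E, S) of a GA-I/CGF-I model by minimizing the
#' OLS objective f(E, S) over windows 1 <= E <= S <= J.  Two search methods
#' are available:
#' \itemize{
#'   \item "exhaustive": every window is evaluated through one cached
#'     basis-curve bank and a vectorized OLS sweep; guarantees the global
#'     minimum (ties resolve to the widest window, so a flat curve returns
#'     (1, J) with theta1 = 0).
#'   \item "greedy": descent from (E, S) = (1, J), at each step evaluating
#'     the window-narrowing proposals (E+1, S) and (E, S-1) and moving to
#'     the smaller if it improves (ties toward (E+1, S)); when neither
#'     improves, the composite step (E+1, S-1) is tried as an escape before
#'     stopping, since the objective surface has diagonal valleys along
#'     which the window center shifts.  Stops at E = S or when no proposal
#'     improves.
#' }
#' "auto" (default) chooses exhaustive when the bank is affordable
#' (J * (J+1) / 2 windows times grid length below ~2e7 entries) and greedy
#' otherwise (e.g. J = 500 on a fine grid).
#'
#' @param Z an \linkS4class{LDCurve}.
#' @param A a \linkS4class{DesignMatrix}.
#' @param model one of "GA-I", "CGF1-I", "CGF2-I".
#' @param m1 source-1 admixture proportion.
#' @param method "auto", "exhaustive" or "greedy".
#' @return a \linkS4class{FitResult} with the fitted (gEnd, gStart).
#' @export
intervalSearch <- function(Z, A, model = c("GA-I", "CGF1-I", "CGF2-I"),
                           m1 = 0.3, method = c("auto", "exhaustive", "greedy")) {
  model <- match.arg(model)
  method <- match.arg(method)
  checkGrid(Z, A)
  z <- asCurveValues(Z)
  J <- ncol(A@A)
  stopifnot(J >= 2)
  if (method == "auto") {
    method <- if (J * (J + 1) / 2 * length(z) <= 2e7) "exhaustive" else "greedy"
  }
  if (method == "exhaustive") {
    bank <- windowBank(model, A, m1)
    ols <- olsMany(z, bank$G)
    k <- which.min(ols$rss)
    return(fitResultFrom(model, bank$idx[k, 1], bank$idx[k, 2], m1,
                         lapply(ols, `[`, k), length(z)))
  }
  memo <- new.env(parent = emptyenv())
  fEval <- function(E, S) {
    key <- paste(E, S)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    x <- as.numeric(A@A %*% windowCoefficients(model, E, S, m1, J))
    fit <- olsLine(z, x)
    memo[[key]] <- fit
    fit
  }
  E <- 1L; S <- J
  cur <- fEval(E, S)
  while (E < S) {
    p1 <- fEval(E + 1L, S)
    p2 <- fEval(E, S - 1L)
    if (min(p1$rss, p2$rss) < cur$rss) {
      if (p1$rss <= p2$rss) { E <- E + 1L; cur <- p1 }
      else { S <- S - 1L; cur <- p2 }
      next
    }
    if (E + 1L <= S - 1L) {
      p3 <- fEval(E + 1L, S - 1L)
      if (p3$rss < cur$rss) { E <- E + 1L; S <- S - 1L; cur <- p3; next }
    }
    break
  }
  fitResultFrom(model, E, S, m1, cur, length(z))
}

#' Fit one core model to a curve
#'
#' Dispatches to \code{\link{scanOnset}} for HI/GA/CGF1/CGF2 and to
#' \code{\link{intervalSearch}} for GA-I/CGF1-I/CGF2-I.
#'
#' @inheritParams scanOnset
#' @param model any core model name.
#' @return a \linkS4class{FitResult}.
#' @export
fitModel <- function(Z, A, model, m1 = 0.3) {
  if (model %in% INTERVAL_MODELS) intervalSearch(Z, A, model, m1)
  else scanOnset(Z, A, model, m1)
}

#' Flexible exponential-mixture reference fit
#'
#' The de-noised reference curve: nonnegative least squares of the observed
#' curve on the full J-column exponential basis with a free offset, solved
#' by alternating the offset update and the NNLS step until the residual
#' sum of squares changes by less than 1e-14 (or 100 iterations).  Its
#' residuals are the denominator of the quasi-F diagnostic.
#'
#' @param Z an \linkS4class{LDCurve}.
#' @param A a \linkS4class{DesignMatrix}.
#' @return a \linkS4class{ReferenceFit}.
#' @export
referenceFit <- function(Z, A) {
  stopifnot(is(A, "DesignMatrix"))
  checkGrid(Z, A)
  z <- asCurveValues(Z)
  # joint NNLS with the free offset carried as a +/- column pair gives the
  # optimum directly; the alternating refinement below then terminates in a
  # step or two and guards the offset/weights split.
  aug <- pracma::lsqnonneg(cbind(A@A, 1, -1), z)$x
  J <- ncol(A@A)
  best <- list(alpha = aug[seq_len(J)], offset = aug[J + 1] - aug[J + 2])
  best$fitted <- as.numeric(A@A %*% best$alpha) + best$offset
  best$rss <- sum((z - best$fitted)^2)
  offset <- best$offset
  for (it in seq_len(100)) {
    alpha <- pracma::lsqnonneg(A@A, z - offset)$x
    fitted0 <- as.numeric(A@A %*% alpha)
    offset <- mean(z - fitted0)
    rss <- sum((z - fitted0 - offset)^2)
    if (rss < best$rss) {
      improved <- best$rss - rss
      best <- list(alpha = alpha, offset = offset, fitted = fitted0 + offset,
                   rss = rss)
      if (improved < 1e-14) break
    } else break
  }
  new("ReferenceFit", alpha = best$alpha, offset = best$offset,
      fitted = best$fitted, rss = best$rss)
}
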