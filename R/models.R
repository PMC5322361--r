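#' Expand a model into a per-generation migration schedule
#'
#' Turns a named admixture model with time window into per-generation
#' migrant fractions from each source:
#' \itemize{
#'   \item HI: a single founding pulse at generation n with fractions
#'     (m1, m2).
#'   \item GA / GA-I: at the t-th generation of the flow window (t = 1 at
#'     gStart) total inflow 1/t, split m1:m2, so every window generation
#'     contributes equally (1/n) to final ancestry.
#'   \item CGF1 / CGF1-I: source 1 is the recipient; the population starts
#'     pure source 1 and receives constant inflow a = 1 - m1^(1/n) from
#'     source 2 at each of the n window generations, so final source-1
#'     ancestry is (1-a)^n = m1.  CGF2 is symmetric with the roles swapped.
#' }
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return a \linkS4class{MigrationSchedule}; its realized present-day
#'   ancestry equals `m1` to within 1e-12.
#' @examples
#' migrationSchedule(modelSpec("HI", 5, 5, 0.3))
#' @export
migrationSchedule <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  gS <- spec@gStart; gE <- spec@gEnd
  n <- gS - gE + 1L
  m1 <- spec@m1; m2 <- 1 - m1
  a1 <- numeric(gS); a2 <- numeric(gS)
  founder <- 1L
  win <- seq(gS, gE)               # generations of the flow window, old -> young
  t <- seq_len(n)                  # position within the window, 1 at gStart
  switch(spec@model,
    "HI" = { a1[gS] <- m1; a2[gS] <- m2 },
    "GA" = , "GA-I" = { a1[win] <- m1 / t; a2[win] <- m2 / t },
    "CGF1" = , "CGF1-I" = {
      founder <- 1L
      a2[win] <- 1 - m1^(1 / n)
    },
    "CGF2" = , "CGF2-I" = {
      founder <- 2L
      a1[win] <- 1 - m2^(1 / n)
    })
  new("MigrationSchedule", alpha1 = a1, alpha2 = a2, founder = founder,
      spec = spec)
}

#' Theoretical ALD coefficient vector for an admixture model
#'
#' Runs the ancestry-covariance recursion forward from the opening of the
#' admixture window to the present.  Writing the ancestry covariance between
#' two loci at distance d as a polynomial in exp(-d), one generation with
#' total migrant inflow a transforms the coefficient ledger as
#' h <- (1 - a) * exp(-d) * h + K, i.e. every ledger entry is damped by
#' (1 - a) and shifted one basis index up (one round of recombination), and
#' a constant injection
#' K = a1 (1 - a1) - 2 a1 (1 - a) m + a (1 - a) m^2
#' (m the pre-transition mean ancestry) enters at basis index 0.  Migrants
#' arriving at generation l thus end at basis index l after their l
#' recombination rounds, and a single pulse at generation n yields the pure
#' exponential exp(-n d).
#'
#' The returned vector is max-normalized; the fitted scale theta1 absorbs
#' absolute magnitude, which depends on source allele-frequency divergence
#' the model need not know.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param J basis size (columns of the design matrix); must be >= gStart.
#' @return a \linkS4class{CoefficientVector} of length J.
#' @examples
#' coefficientVector(modelSpec("HI", 5, 5, 0.3), J = 10)
#' @export
coefficientVector <- function(spec, J = 500L) {
  stopifnot(is(spec, "ModelSpec"))
  J <- as.integer(J)
  if (spec@gStart > J)
    stop(sprintf("admixture window reaches %d generations but J = %d; raise J",
                 spec@gStart, J))
  sched <- migrationSchedule(spec)
  C <- ledgerRecursion(sched@alpha1, sched@alpha2, sched@founder, J)
  if (max(C) <= 0) stop("degenerate model: no admixture LD injected")
  new("CoefficientVector", coef = C / max(C), spec = spec)
}

# The generic ledger recursion for an arbitrary migration schedule.
# Returns the unnormalized coefficient vector on basis indices 1..J.
ledgerRecursion <- function(alpha1, alpha2, founder, J) {
  gS <- length(alpha1)
  c0 <- 0                       # basis index 0 (constant term)
  C <- numeric(J)
  m <- if (founder == 1L) 1 else 0
  for (g in seq(gS, 0)) {       # transition forming the state at generation g
    a1 <- if (g >= 1) alpha1[g] else 0
    a2 <- if (g >= 1) alpha2[g] else 0
    a <- a1 + a2; b <- 1 - a
    K <- a1 * (1 - a1) - 2 * a1 * b * m + a * b * m^2
    if (C[J] != 0) stop("ledger index exceeds J; raise J")
    C <- c(b * c0, b * C[-J])
    c0 <- K
    m <- a1 + b * m
  }
  C
}

# Closed-form (per-model) coefficient vectors, unnormalized, as a function of
# the window (E, S).  Algebraically identical to ledgerRecursion on the
# schedules produced by migrationSchedule(); used for fast window scans.
#   HI(n):       spike m1 m2 at index n.
#   GA-I(E,S):   flat m1 m2 / n over [E, S].
#   CGF1-I(E,S): C[l] = a (1-a)^(n + S - l), a = 1 - m1^(1/n), l in [E, S].
#   CGF2-I:      same with m1 replaced by m2 = 1 - m1.
windowCoefficients <- function(model, E, S, m1, J) {
  n <- S - E + 1L
  C <- numeric(J)
  win <- seq(E, S)
  m2 <- 1 - m1
  if (model == "HI") {
    C[S] <- m1 * m2
  } else if (model %in% c("GA", "GA-I")) {
    C[win] <- m1 * m2 / n
  } else if (model %in% c("CGF1", "CGF1-I")) {
    a <- 1 - m1^(1 / n)
    C[win] <- a * (1 - a)^(n + S - win)
  } else if (model %in% c("CGF2", "CGF2-I")) {
    a <- 1 - m2^(1 / n)
    C[win] <- a * (1 - a)^(n + S - win)
  } else stop("unknown model")
  C
}

#' Evaluate a model ALD curve on a distance grid
#'
#' value_i = theta1 * sum_l C[l] exp(-l d_i) + theta0.
#'
#' @param C a \linkS4class{CoefficientVector}.
#' @param d distance grid, Morgans, all > 0.
#' @param theta0 offset correcting population substructure.
#' @param theta1 scale.
#' @return numeric curve values.
#' @examples
#' modelCurve(coefficientVector(modelSpec("HI", 5, 5, 0.3), 10), d = 0.1)
#' @export
modelCurve <- function(C, d, theta0 = 0, theta1 = 1) {
  stopifnot(is(C, "CoefficientVector"), all(d > 0))
  J <- length(C@coef)
  as.numeric(theta1 * (exp(-outer(as.numeric(d), seq_len(J))) %*% C@coef) + theta0)
}
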