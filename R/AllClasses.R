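#' @import methods
NULL

MODEL_NAMES <- c("HI", "GA", "CGF1", "CGF2", "GA-I", "CGF1-I", "CGF2-I")
INTERVAL_MODELS <- c("GA-I", "CGF1-I", "CGF2-I")

#' HaplotypePanel: a haplotype or genotype matrix with a genetic map
#'
#' Holds one population panel: a haplotypes-by-sites matrix of allele values
#' together with per-site chromosome labels and genetic positions in
#' Morgans.  `ploidy = 1` means rows are phased haplotypes with alleles in
#' \{0, 1\}; `ploidy = 2` means rows are diploid individuals carrying allele
#' dosages in \{0, 1, 2\}.  Dosages are sufficient for all computations in
#' the package (allele frequencies and covariances); phase is never required.
#' Sites are stored sorted by chromosome and genetic position.
#'
#' @slot alleles numeric matrix, haplotypes (or individuals) x sites.
#' @slot chrom character vector, per-site chromosome label.
#' @slot gpos numeric vector, per-site genetic position in Morgans.
#' @slot ploidy integer, 1 (haplotypes) or 2 (genotype dosages).
#' @slot popLabel character, one of "admixed", "source1", "source2".
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(alleles = "matrix", chrom = "character", gpos = "numeric",
                 ploidy = "integer", popLabel = "character"))

setValidity("HaplotypePanel", function(object) {
  a <- object@alleles
  if (ncol(a) != length(object@chrom) || ncol(a) != length(object@gpos))
    return("site metadata length must equal ncol(alleles)")
  if (nrow(a) < 2) return("need at least 2 haplotypes/individuals")
  if (!(object@ploidy %in% c(1L, 2L))) return("ploidy must be 1 or 2")
  ok <- is.na(a) | (a >= 0 & a <= object@ploidy & a == round(a))
  if (!all(ok)) return("allele values must be integers in [0, ploidy] or NA")
  for (cc in unique(object@chrom)) {
    g <- object@gpos[object@chrom == cc]
    if (is.unsorted(g)) return(sprintf("gpos not non-decreasing on chromosome %s", cc))
  }
  if (length(object@popLabel) != 1) return("popLabel must be a single string")
  TRUE
})

#' Construct a HaplotypePanel
#'
#' @param alleles haplotypes-by-sites matrix of 0/1 alleles (ploidy 1) or
#'   0/1/2 dosages (ploidy 2); NA for missing.
#' @param chrom per-site chromosome labels.
#' @param gpos per-site genetic positions, Morgans.
#' @param ploidy 1 for haplotypes, 2 for genotype dosages.
#' @param popLabel "admixed", "source1" or "source2".
#' @return a \linkS4class{HaplotypePanel}; sites are reordered by
#'   (chromosome, genetic position).
#' @export
HaplotypePanel <- function(alleles, chrom, gpos, ploidy = 1L,
                           popLabel = "admixed") {
  chrom <- as.character(chrom)
  o <- order(match(chrom, unique(chrom)), gpos)
  new("HaplotypePanel", alleles = as.matrix(alleles)[, o, drop = FALSE],
      chrom = chrom[o], gpos = as.numeric(gpos)[o],
      ploidy = as.integer(ploidy), popLabel = popLabel)
}

#' @rdname camix-generics
#' @export
setMethod("nSites", "HaplotypePanel", function(x) ncol(x@alleles))
#' @rdname camix-generics
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@alleles))

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel '%s': %d %s x %d sites on %d chromosome(s)\n",
              object@popLabel, nrow(object@alleles),
              if (object@ploidy == 1L) "haplotypes" else "individuals",
              ncol(object@alleles), length(unique(object@chrom))))
})

#' LDCurve: a binned weighted-LD decay curve
#'
#' @slot d distance-bin midpoints, Morgans, strictly increasing and > 0.
#' @slot z curve values (covariance units, dimensionless).
#' @slot nPairs number of site pairs per bin.
#' @slot label "full" or "drop_chrom:<c>".
#' @exportClass LDCurve
setClass("LDCurve",
  representation(d = "numeric", z = "numeric", nPairs = "numeric",
                 label = "character"))

setValidity("LDCurve", function(object) {
  if (length(object@d) != length(object@z) ||
      length(object@d) != length(object@nPairs))
    return("d, z, nPairs must have equal length")
  if (length(object@d) == 0) return("empty curve")
  if (any(object@d <= 0)) return("d must be > 0")
  if (any(diff(object@d) <= 0)) {
    i <- which(diff(object@d) <= 0)[1] + 1
    return(sprintf("d not strictly increasing at row %d", i))
  }
  if (any(!is.finite(object@z))) return("z must be finite")
  if (any(object@nPairs < 1)) return("every retained bin needs nPairs >= 1")
  TRUE
})

#' Construct an LDCurve
#' @param d distance-bin midpoints, Morgans.
#' @param z curve values.
#' @param nPairs pairs per bin (default 1).
#' @param label curve label.
#' @return an \linkS4class{LDCurve}.
#' @export
LDCurve <- function(d, z, nPairs = rep(1, length(d)), label = "full")
  new("LDCurve", d = as.numeric(d), z = as.numeric(z),
      nPairs = as.numeric(nPairs), label = label)

#' @rdname camix-generics
#' @export
setMethod("curveDist", "LDCurve", function(x) x@d)
#' @rdname camix-generics
#' @export
setMethod("curveValues", "LDCurve", function(x) x@z)
#' @rdname camix-generics
#' @export
setMethod("pairCounts", "LDCurve", function(x) x@nPairs)

setMethod("show", "LDCurve", function(object) {
  cat(sprintf("LDCurve '%s': %d bins, d in [%.4g, %.4g] M\n", object@label,
              length(object@d), min(object@d), max(object@d)))
})

#' LDCurveSet: full-genome ALD curve plus leave-one-chromosome-out curves
#'
#' @slot full the full-genome \linkS4class{LDCurve}.
#' @slot jackknives list of N leave-one-chromosome-out curves.
#' @slot m1 admixture proportion of source 1, in (0, 1).
#' @exportClass LDCurveSet
setClass("LDCurveSet",
  representation(full = "LDCurve", jackknives = "list", m1 = "numeric"))

setValidity("LDCurveSet", function(object) {
  if (length(object@jackknives) < 2) return("need N >= 2 jackknife curves")
  if (!(object@m1 > 0 && object@m1 < 1)) return("m1 must be in (0,1)")
  d0 <- object@full@d
  for (jc in object@jackknives) {
    if (!is(jc, "LDCurve")) return("jackknives must be LDCurve objects")
    if (length(jc@d) != length(d0) || any(jc@d != d0))
      return("all curves must share the same distance grid")
  }
  TRUE
})

#' Construct an LDCurveSet
#' @param full full-genome curve.
#' @param jackknives list of leave-one-chromosome-out curves.
#' @param m1 admixture proportion of source 1.
#' @return an \linkS4class{LDCurveSet}.
#' @export
LDCurveSet <- function(full, jackknives, m1)
  new("LDCurveSet", full = full, jackknives = jackknives, m1 = m1)

#' @rdname camix-generics
#' @export
setMethod("admixtureProportion", "LDCurveSet", function(x) x@m1)

setMethod("show", "LDCurveSet", function(object) {
  cat(sprintf("LDCurveSet: %d bins, %d jackknives, m1 = %.3f\n",
              length(object@full@d), length(object@jackknives), object@m1))
})

#' ModelSpec: an admixture model with its time window
#'
#' Models: HI (one pulse), GA (gradual admixture from both sources), CGF1 /
#' CGF2 (continuous gene flow, source 1 / source 2 as recipient), and their
#' isolation-truncated forms GA-I, CGF1-I, CGF2-I.  The admixture window
#' runs from `gStart` generations before present (onset) to `gEnd`
#' generations before present (end of gene flow); for HI, gEnd == gStart.
#' For GA/CGF1/CGF2 the window always reaches the present (gEnd == 1).
#'
#' @slot model one of "HI","GA","CGF1","CGF2","GA-I","CGF1-I","CGF2-I".
#' @slot gEnd generations before present at which gene flow stopped.
#' @slot gStart generations before present at which gene flow began.
#' @slot m1 final source-1 ancestry proportion, in (0, 1).
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(model = "character", gEnd = "integer", gStart = "integer",
                 m1 = "numeric"))

setValidity("ModelSpec", function(object) {
  if (!(object@model %in% MODEL_NAMES))
    return(sprintf("unknown model '%s'", object@model))
  if (object@gEnd < 1 || object@gEnd > object@gStart)
    return("need 1 <= gEnd <= gStart")
  if (object@model == "HI" && object@gEnd != object@gStart)
    return("HI requires gEnd == gStart")
  if (object@model %in% c("GA", "CGF1", "CGF2") && object@gEnd != 1)
    return(sprintf("%s requires gEnd == 1 (flow to the present)", object@model))
  if (!(object@m1 > 0 && object@m1 < 1)) return("m1 must be in (0,1)")
  TRUE
})

#' Construct a ModelSpec
#' @param model model name.
#' @param gEnd end of gene flow, generations before present.
#' @param gStart onset of gene flow, generations before present.
#' @param m1 final source-1 ancestry proportion.
#' @return a \linkS4class{ModelSpec}.
#' @examples
#' modelSpec("HI", 50, 50, 0.3)
#' modelSpec("GA-I", 30, 100, 0.3)
#' @export
modelSpec <- function(model, gEnd, gStart = gEnd, m1 = 0.3)
  new("ModelSpec", model = model, gEnd = as.integer(gEnd),
      gStart = as.integer(gStart), m1 = m1)

#' @rdname camix-generics
#' @export
setMethod("modelName", "ModelSpec", function(x) x@model)
#' @rdname camix-generics
#' @export
setMethod("timeWindow", "ModelSpec", function(x) c(gEnd = x@gEnd, gStart = x@gStart))
#' @rdname camix-generics
#' @export
setMethod("admixtureProportion", "ModelSpec", function(x) x@m1)

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("%s(%s), m1 = %.3f\n", object@model,
              if (object@gEnd == object@gStart) object@gEnd
              else sprintf("%d-%d", object@gEnd, object@gStart), object@m1))
})

#' MigrationSchedule: per-generation migrant fractions
#'
#' Element l of `alpha1`/`alpha2` is the fraction of the population replaced
#' by unadmixed migrants from source 1/2 at generation l before present.
#' `founder` gives the ancestry (1 or 2) of the population before the
#' admixture window opens (relevant for CGF, where the recipient pre-exists).
#'
#' @slot alpha1 numeric, length gStart; migrant fraction from source 1.
#' @slot alpha2 numeric, length gStart; migrant fraction from source 2.
#' @slot founder integer, 1 or 2.
#' @slot spec the originating \linkS4class{ModelSpec}.
#' @exportClass MigrationSchedule
setClass("MigrationSchedule",
  representation(alpha1 = "numeric", alpha2 = "numeric", founder = "integer",
                 spec = "ModelSpec"))

setValidity("MigrationSchedule", function(object) {
  a1 <- object@alpha1; a2 <- object@alpha2
  if (length(a1) != length(a2)) return("alpha1/alpha2 length mismatch")
  if (length(a1) != object@spec@gStart) return("schedule length must be gStart")
  if (any(a1 < 0) || any(a2 < 0) || any(a1 + a2 > 1 + 1e-12))
    return("need 0 <= alpha1[l] + alpha2[l] <= 1")
  win <- seq(object@spec@gEnd, object@spec@gStart)
  if (any((a1 + a2)[-win] != 0) && length(a1) > length(win))
    return("migrant fractions outside [gEnd, gStart] must be 0")
  if (abs(realizedAncestry(object) - object@spec@m1) > 1e-12)
    return("schedule does not realize the specified m1")
  TRUE
})

setMethod("show", "MigrationSchedule", function(object) {
  cat(sprintf("MigrationSchedule for %s(%d-%d): founder source %d, m1 = %.3f\n",
              object@spec@model, object@spec@gEnd, object@spec@gStart,
              object@founder, object@spec@m1))
})

#' Present-day source-1 ancestry realized by a migration schedule
#'
#' Propagates the ancestry recursion m <- alpha1 + (1 - alpha1 - alpha2) * m
#' from the pre-admixture founder population to the present.
#'
#' @param schedule a \linkS4class{MigrationSchedule}.
#' @return the present-day source-1 ancestry proportion.
#' @export
realizedAncestry <- function(schedule) {
  m <- if (schedule@founder == 1L) 1 else 0
  for (l in seq(schedule@spec@gStart, 1)) {
    a1 <- schedule@alpha1[l]; a2 <- schedule@alpha2[l]
    m <- a1 + (1 - a1 - a2) * m
  }
  m
}

#' CoefficientVector: theoretical ALD shape in the exp(-l d) basis
#'
#' Entry l multiplies exp(-l * d); the vector is max-normalized (the fitted
#' scale theta1 absorbs absolute magnitude).
#'
#' @slot coef numeric length-J coefficient vector, nonnegative, max = 1.
#' @slot spec the originating \linkS4class{ModelSpec}.
#' @exportClass CoefficientVector
setClass("CoefficientVector",
  representation(coef = "numeric", spec = "ModelSpec"))

setValidity("CoefficientVector", function(object) {
  C <- object@coef
  if (any(C < 0)) return("coefficients must be nonnegative")
  if (abs(max(C) - 1) > 1e-9) return("max entry must be normalized to 1")
  s <- object@spec
  idx <- which(C > 0)
  if (length(idx) && (min(idx) < s@gEnd || max(idx) > s@gStart))
    return("support must lie within [gEnd, gStart]")
  TRUE
})

#' @rdname camix-generics
#' @export
setMethod("modelName", "CoefficientVector", function(x) x@spec@model)

setMethod("show", "CoefficientVector", function(object) {
  cat(sprintf("CoefficientVector %s(%d-%d): J = %d, support [%d, %d]\n",
              object@spec@model, object@spec@gEnd, object@spec@gStart,
              length(object@coef), min(which(object@coef > 0)),
              max(which(object@coef > 0))))
})

#' DesignMatrix: exponential-decay basis evaluated on a distance grid
#'
#' @slot A I x J matrix with A[i, l] = exp(-l * d_i).
#' @slot d the distance grid, Morgans.
#' @exportClass DesignMatrix
setClass("DesignMatrix", representation(A = "matrix", d = "numeric"))

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d distances x J = %d\n",
              nrow(object@A), ncol(object@A)))
})

#' FitResult: one model fitted to one ALD curve
#'
#' @slot spec fitted \linkS4class{ModelSpec} (times filled in).
#' @slot theta0 offset (substructure correction).
#' @slot theta1 scale.
#' @slot rss residual sum of squares (the objective f).
#' @slot msE mean squared residual.
#' @slot quasiF residual-ratio diagnostic vs the reference fit (NA until set).
#' @slot degenerate TRUE when the model curve was numerically constant and
#'   theta1 was forced to 0.
#' @exportClass FitResult
setClass("FitResult",
  representation(spec = "ModelSpec", theta0 = "numeric", theta1 = "numeric",
                 rss = "numeric", msE = "numeric", quasiF = "numeric",
                 degenerate = "logical"))

setValidity("FitResult", function(object) {
  if (object@msE < 0) return("msE must be >= 0")
  if (!is.na(object@quasiF) && object@quasiF < 0) return("quasiF must be >= 0")
  TRUE
})

#' @rdname camix-generics
#' @export
setMethod("modelName", "FitResult", function(x) x@spec@model)
#' @rdname camix-generics
#' @export
setMethod("timeWindow", "FitResult", function(x) timeWindow(x@spec))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult %s(%d-%d): theta0 = %.3g, theta1 = %.3g, msE = %.3g%s\n",
              object@spec@model, object@spec@gEnd, object@spec@gStart,
              object@theta0, object@theta1, object@msE,
              if (!is.na(object@quasiF)) sprintf(", quasi-F = %.3g", object@quasiF)
              else ""))
})

#' ReferenceFit: flexible nonnegative exponential-mixture fit
#'
#' The de-noised reference curve: nonnegative least squares on the full
#' J-column exponential basis with a free offset.
#'
#' @slot alpha length-J nonnegative mixture weights.
#' @slot offset fitted offset.
#' @slot fitted fitted curve values on the distance grid.
#' @slot rss residual sum of squares.
#' @exportClass ReferenceFit
setClass("ReferenceFit",
  representation(alpha = "numeric", offset = "numeric", fitted = "numeric",
                 rss = "numeric"))

setValidity("ReferenceFit", function(object) {
  if (any(object@alpha < 0)) return("mixture weights must be nonnegative")
  TRUE
})

setMethod("show", "ReferenceFit", function(object) {
  cat(sprintf("ReferenceFit: %d active components, rss = %.3g\n",
              sum(object@alpha > 0), object@rss))
})

#' SelectionReport: jackknife model-selection result
#'
#' @slot pseudo N x M matrix of pseudo log(msE) values.
#' @slot adjP symmetric matrix of Holm-adjusted pairwise Wilcoxon p-values.
#' @slot bestSet selected model name(s).
#' @slot undetermined TRUE when more than one model was selected.
#' @slot timeSummary data.frame: per-model time interval summarized over
#'   jackknives.
#' @slot diagnostics data.frame: per-model full-curve fit with msE, quasi-F
#'   and threshold flags.
#' @slot fits list of per-model full-curve \linkS4class{FitResult}s.
#' @slot alpha significance level used.
#' @exportClass SelectionReport
setClass("SelectionReport",
  representation(pseudo = "matrix", adjP = "matrix", bestSet = "character",
                 undetermined = "logical", timeSummary = "data.frame",
                 diagnostics = "data.frame", fits = "list", alpha = "numeric"))

setValidity("SelectionReport", function(object) {
  if (length(object@bestSet) < 1) return("bestSet must be nonempty")
  if (object@undetermined != (length(object@bestSet) > 1))
    return("undetermined must equal |bestSet| > 1")
  p <- object@adjP
  if (nrow(p) != ncol(p)) return("adjP must be square")
  off <- p[upper.tri(p) | lower.tri(p)]
  if (any(!is.na(off) & (off < 0 | off > 1))) return("adjP entries must be in [0,1]")
  TRUE
})

#' @rdname camix-generics
#' @export
setMethod("bestModels", "SelectionReport", function(x) x@bestSet)
#' @rdname camix-generics
#' @export
setMethod("isUndetermined", "SelectionReport", function(x) x@undetermined)

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: best-fit model(s) %s%s\n",
              paste(object@bestSet, collapse = ", "),
              if (object@undetermined) " (undetermined)" else ""))
  print(object@diagnostics, row.names = FALSE)
})

#' SourcePanelModel: synthetic source-panel allele-frequency model
#'
#' A Balding-Nichols-style stand-in for a diverged source-population pair:
#' per-site ancestral frequencies are uniform on (freqMin, freqMax) and the
#' two source frequencies are Beta-distributed around them with divergence
#' parameter F (Fst-like).  This is a synthetic stand-in for real source
#' panels, not a claim of equivalence to any particular population pair.
#'
#' @slot nSites sites per chromosome.
#' @slot divergence Balding-Nichols F, in (0, 1).
#' @slot freqMin,freqMax ancestral-frequency range.
#' @exportClass SourcePanelModel
setClass("SourcePanelModel",
  representation(nSites = "integer", divergence = "numeric",
                 freqMin = "numeric", freqMax = "numeric"))

setValidity("SourcePanelModel", function(object) {
  if (!(object@divergence > 0 && object@divergence < 1))
    return("divergence must be in (0,1)")
  if (object@nSites < 2) return("need at least 2 sites per chromosome")
  if (!(object@freqMin > 0 && object@freqMax < 1 && object@freqMin < object@freqMax))
    return("need 0 < freqMin < freqMax < 1")
  TRUE
})

#' Construct a SourcePanelModel
#' @param nSites sites per chromosome (default 1000 per 0.3-Morgan chromosome).
#' @param divergence Balding-Nichols F (default 0.15, an African-European-like
#'   stand-in).
#' @param freqMin,freqMax ancestral allele-frequency range.
#' @return a \linkS4class{SourcePanelModel}.
#' @export
sourcePanelModel <- function(nSites = 1000L, divergence = 0.15,
                             freqMin = 0.05, freqMax = 0.95)
  new("SourcePanelModel", nSites = as.integer(nSites), divergence = divergence,
      freqMin = freqMin, freqMax = freqMax)

#' SimConfig: forward-time simulation settings
#'
#' @slot schedule the \linkS4class{MigrationSchedule} to simulate.
#' @slot popSize haploid population size (default 5000).
#' @slot chromLengths chromosome lengths in Morgans (default 10 x 0.3).
#' @slot nSample number of present-day haplotypes returned.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(schedule = "MigrationSchedule", popSize = "integer",
                 chromLengths = "numeric", nSample = "integer"))

setValidity("SimConfig", function(object) {
  if (object@popSize < 2L * object@nSample)
    return("popSize must be >= 2 * nSample")
  if (any(object@chromLengths <= 0)) return("chromosome lengths must be > 0")
  if (object@schedule@spec@gStart > 500)
    return("admixture window must be <= 500 generations")
  TRUE
})

#' Construct a SimConfig
#' @param schedule a \linkS4class{MigrationSchedule}.
#' @param popSize haploid population size.
#' @param chromLengths chromosome lengths, Morgans.
#' @param nSample sampled haplotypes.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(schedule, popSize = 5000L,
                      chromLengths = rep(0.3, 10), nSample = 200L)
  new("SimConfig", schedule = schedule, popSize = as.integer(popSize),
      chromLengths = as.numeric(chromLengths), nSample = as.integer(nSample))

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %s, pop %d, %d chromosome(s) totaling %.2f M, %d sampled\n",
              sprintf("%s(%d-%d)", object@schedule@spec@model,
                      object@schedule@spec@gEnd, object@schedule@spec@gStart),
              object@popSize, length(object@chromLengths),
              sum(object@chromLengths), object@nSample))
})

#' TractSample: sampled ancestry-tract haplotypes
#'
#' @slot tracts data.frame with columns chrom, hap, start, end, ancestry;
#'   tracts tile each (hap, chromosome) exactly.
#' @slot chromLengths chromosome lengths, Morgans.
#' @slot nHap number of sampled haplotypes.
#' @exportClass TractSample
setClass("TractSample",
  representation(tracts = "data.frame", chromLengths = "numeric",
                 nHap = "integer"))

setValidity("TractSample", function(object) {
  tr <- object@tracts
  need <- c("chrom", "hap", "start", "end", "ancestry")
  if (!all(need %in% names(tr))) return("tracts missing required columns")
  if (any(tr$end <= tr$start)) return("tracts must have end > start")
  if (!all(tr$ancestry %in% c(1L, 2L))) return("ancestry labels must be 1 or 2")
  TRUE
})

#' @rdname camix-generics
#' @export
setMethod("nHaplotypes", "TractSample", function(x) x@nHap)

setMethod("show", "TractSample", function(object) {
  cat(sprintf("TractSample: %d haplotypes, %d chromosome(s), %d tracts, mean source-1 ancestry %.3f\n",
              object@nHap, length(object@chromLengths), nrow(object@tracts),
              ancestryProportion(object)))
})

#' Realized source-1 ancestry proportion of a tract sample
#' @param x a \linkS4class{TractSample}.
#' @return length-weighted fraction of genome with source-1 ancestry.
#' @export
ancestryProportion <- function(x) {
  tr <- x@tracts
  len <- tr$end - tr$start
  sum(len[tr$ancestry == 1L]) / sum(len)
}
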