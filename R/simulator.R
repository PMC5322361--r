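#' Forward-time ancestry-tract simulation
#'
#' Simulates a two-way admixed population under an arbitrary migration
#' schedule with the copying model: each generation, every offspring
#' haplotype is either a whole unadmixed migrant haplotype (with the
#' schedule's per-generation probabilities) or a recombinant of two random
#' haplotypes of the previous generation, with crossovers a Poisson process
#' of rate 1 per Morgan (uniform recombination map).  Chromosomes evolve
#' independently.  Migrants entering at generation l experience exactly l
#' recombination rounds before sampling, matching the exp(-l d) basis of
#' the theoretical curves.  Uses R's RNG: call set.seed() for
#' reproducibility.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{TractSample} of config@nSample haplotypes.
#' @examples
#' set.seed(1)
#' sim <- simulateTracts(simConfig(migrationSchedule(modelSpec("HI", 20, 20, 0.3)),
#'                                 popSize = 400L, chromLengths = rep(0.3, 2),
#'                                 nSample = 100L))
#' ancestryProportion(sim)
#' @export
simulateTracts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  sch <- config@schedule
  tr <- .simulate_tracts_cpp(sch@alpha1, sch@alpha2, sch@founder,
                             config@popSize, config@chromLengths,
                             config@nSample)
  if (nrow(tr) == 0) stop("empty population: simulation produced no tracts")
  new("TractSample", tracts = tr, chromLengths = config@chromLengths,
      nHap = config@nSample)
}

# Ancestry-indicator matrix (nHap x nSite, values 1/2) on given site grid.
ancestryMatrix <- function(sample, siteGpos, siteChrom) {
  tr <- sample@tracts
  .ancestry_matrix_cpp(as.integer(tr$chrom), as.integer(tr$hap),
                       tr$start, tr$end, as.integer(tr$ancestry),
                       sample@nHap, siteGpos, as.integer(siteChrom))
}

evenSiteGrid <- function(chromLengths, nLoci) {
  gpos <- unlist(lapply(chromLengths, function(L)
    seq(0, L, length.out = nLoci + 2)[seq(2, nLoci + 1)]))
  list(gpos = gpos, chrom = rep(seq_along(chromLengths), each = nLoci))
}

#' Binned ancestry-indicator LD curve of a tract sample
#'
#' Evaluates source-1 ancestry indicators on an evenly spaced locus grid and
#' computes the binned covariance products exactly as the weighted-LD
#' machinery with unit weights.  This is the fully-diverged limit of the
#' weighted LD curve and serves as the simulation oracle for the
#' theoretical coefficient vectors.
#'
#' @param sample a \linkS4class{TractSample} with >= 100 haplotypes.
#' @param bins a \code{\link{binSpec}}.
#' @param nLoci loci per chromosome of the evaluation grid.
#' @return an \linkS4class{LDCurve}.
#' @export
ancestryLDCurve <- function(sample, bins = binSpec(), nLoci = 100L) {
  stopifnot(is(sample, "TractSample"), sample@nHap >= 100)
  grid <- evenSiteGrid(sample@chromLengths, as.integer(nLoci))
  anc <- ancestryMatrix(sample, grid$gpos, grid$chrom)
  panel <- new("HaplotypePanel", alleles = (anc == 1L) * 1.0,
               chrom = as.character(grid$chrom), gpos = grid$gpos,
               ploidy = 1L, popLabel = "admixed")
  weightedLDCurve(panel, rep(1, length(grid$gpos)), bins)
}

#' Paint tract haplotypes into SNP panels
#'
#' Draws per-site source allele frequencies from the Balding-Nichols-style
#' divergence model and simulates the two source panels by Bernoulli
#' sampling.  Admixed alleles are then painted from the local ancestry
#' labels by one of two schemes:
#' \itemize{
#'   \item "frequency" (default): each admixed allele is an independent
#'     Bernoulli draw from the source-specific frequency selected by the
#'     local ancestry label; frequencies and covariances, all the method
#'     consumes, are faithful by construction.
#'   \item "copy": each ancestry tract copies the allele slice of a
#'     randomly chosen haplotype of the matching source panel, mimicking
#'     the resampling-with-recombination scheme used to build admixed
#'     haplotypes from real source panels; background structure present in
#'     the source panels is then carried into the admixed sample and
#'     partially cancels in the ALD combination z = a0 - m1 a1 - m2 a2.
#' }
#'
#' @param sample a \linkS4class{TractSample}.
#' @param panelModel a \linkS4class{SourcePanelModel}.
#' @param nSourceHap haplotypes per source panel (default 226).
#' @param method painting scheme, "copy" or "frequency".
#' @return list of three \linkS4class{HaplotypePanel}s: admixed, source1,
#'   source2.  Uses R's RNG: call set.seed() for reproducibility.
#' @export
paintHaplotypes <- function(sample, panelModel = sourcePanelModel(),
                            nSourceHap = 226L,
                            method = c("frequency", "copy")) {
  stopifnot(is(sample, "TractSample"), is(panelModel, "SourcePanelModel"))
  method <- match.arg(method)
  nSites <- panelModel@nSites
  grid <- evenSiteGrid(sample@chromLengths, nSites)
  total <- length(grid$gpos)

  pAnc <- runif(total, panelModel@freqMin, panelModel@freqMax)
  Fst <- panelModel@divergence
  shape <- (1 - Fst) / Fst
  p1 <- rbeta(total, pAnc * shape, (1 - pAnc) * shape)
  p2 <- rbeta(total, pAnc * shape, (1 - pAnc) * shape)

  drawPanel <- function(p, nHap, label) {
    m <- matrix(rbinom(nHap * total, 1L, rep(p, each = nHap)), nrow = nHap)
    new("HaplotypePanel", alleles = m * 1.0,
        chrom = as.character(grid$chrom), gpos = grid$gpos, ploidy = 1L,
        popLabel = label)
  }
  s1 <- drawPanel(p1, nSourceHap, "source1")
  s2 <- drawPanel(p2, nSourceHap, "source2")

  if (method == "frequency") {
    anc <- ancestryMatrix(sample, grid$gpos, grid$chrom)
    pMat <- matrix(p1, nrow = sample@nHap, ncol = total, byrow = TRUE)
    p2Mat <- matrix(p2, nrow = sample@nHap, ncol = total, byrow = TRUE)
    pMat[anc == 2L] <- p2Mat[anc == 2L]
    adm <- matrix(rbinom(length(pMat), 1L, pMat), nrow = sample@nHap)
  } else {
    tr <- sample@tracts
    donor <- sample.int(nSourceHap, nrow(tr), replace = TRUE)
    adm <- .copy_paint_cpp(as.integer(tr$chrom), as.integer(tr$hap),
                           tr$start, tr$end, as.integer(tr$ancestry),
                           donor, sample@nHap, s1@alleles, s2@alleles,
                           grid$gpos, as.integer(grid$chrom))
  }
  admixed <- new("HaplotypePanel", alleles = adm * 1.0,
                 chrom = as.character(grid$chrom), gpos = grid$gpos,
                 ploidy = 1L, popLabel = "admixed")
  list(admixed = admixed, source1 = s1, source2 = s2)
}

#' Simulate a painted panel set under a model
#'
#' Convenience wrapper: schedule -> tract simulation -> painted panels.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param popSize haploid population size.
#' @param chromLengths chromosome lengths, Morgans.
#' @param nSample admixed haplotypes to sample.
#' @param panelModel a \linkS4class{SourcePanelModel}.
#' @param nSourceHap haplotypes per source panel.
#' @param paintMethod painting scheme passed to \code{\link{paintHaplotypes}}.
#' @return list with elements `panels` (admixed/source1/source2) and
#'   `tracts` (the \linkS4class{TractSample}).
#' @export
simulatePanels <- function(spec, popSize = 5000L, chromLengths = rep(0.3, 10),
                           nSample = 200L, panelModel = sourcePanelModel(),
                           nSourceHap = 226L,
                           paintMethod = c("frequency", "copy")) {
  sim <- simulateTracts(simConfig(migrationSchedule(spec), popSize,
                                  chromLengths, nSample))
  list(panels = paintHaplotypes(sim, panelModel, nSourceHap,
                                method = match.arg(paintMethod)),
       tracts = sim)
}

#' Write a test fixture to disk
#'
#' Generates and writes a fixture of the requested kind with provenance
#' metadata (model, seed) embedded as comment lines:
#' \itemize{
#'   \item "noiseless_curve"/"noisy_curve": a curve-set TSV whose full and
#'     jackknife curves are the theoretical model curve (plus Gaussian noise
#'     of sd `noiseSd` for the noisy kind),
#'   \item "panel_set": plain haplotype matrices plus a map file from a
#'     small forward simulation.
#' }
#'
#' @param kind fixture kind.
#' @param spec a \linkS4class{ModelSpec}.
#' @param dir output directory (created if needed).
#' @param noiseSd Gaussian noise sd on curve values (noisy_curve only).
#' @param seed RNG seed.
#' @param nJack number of jackknife curves for curve fixtures.
#' @param theta0,theta1 curve offset and scale for curve fixtures.
#' @param bins a \code{\link{binSpec}}.
#' @param J basis size for curve evaluation.
#' @return (invisibly) the paths written.
#' @export
makeFixture <- function(kind = c("noiseless_curve", "noisy_curve", "panel_set"),
                        spec, dir, noiseSd = 0, seed = 1, nJack = 10L,
                        theta0 = 1e-4, theta1 = 5e-3, bins = binSpec(),
                        J = NULL) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  meta <- sprintf("# model=%s gEnd=%d gStart=%d m1=%g seed=%d",
                  spec@model, spec@gEnd, spec@gStart, spec@m1, seed)
  if (kind %in% c("noiseless_curve", "noisy_curve")) {
    sd <- if (kind == "noiseless_curve") 0 else noiseSd
    if (is.null(J)) J <- max(100L, spec@gStart)
    C <- coefficientVector(spec, J)
    base <- modelCurve(C, bins$mid, theta0, theta1)
    mk <- function(label) LDCurve(bins$mid, base + rnorm(length(base), 0, sd),
                                  label = label)
    cs <- LDCurveSet(mk("full"),
                     lapply(seq_len(nJack), function(q)
                       mk(paste0("drop_chrom:", q))), spec@m1)
    path <- file.path(dir, sprintf("%s_%s.tsv", spec@model, kind))
    writeCurveSet(cs, path, extraHeader = meta)
    return(invisible(path))
  }
  sim <- simulatePanels(spec, popSize = 500L, chromLengths = rep(0.3, 3),
                        nSample = 60L,
                        panelModel = sourcePanelModel(nSites = 100L),
                        nSourceHap = 60L)
  paths <- writePanelSet(sim$panels, dir, extraHeader = meta)
  invisible(paths)
}
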