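#' Scenarios of the model-determination accuracy study
#'
#' The ten simulated admixture histories evaluated by the accuracy study:
#' one-pulse admixture 50 and 100 generations ago, gradual admixture and
#' continuous gene flow over the last 50 or 100 generations, and
#' isolation-truncated histories with gene flow windows 30-100 and 70-100
#' generations ago, all at final source-1 proportion 0.3.
#'
#' @return a list of \linkS4class{ModelSpec}s.
#' @export
studyScenarios <- function() {
  list(modelSpec("HI", 50, 50, 0.3),
       modelSpec("HI", 100, 100, 0.3),
       modelSpec("GA", 1, 50, 0.3),
       modelSpec("GA", 1, 100, 0.3),
       modelSpec("CGF1", 1, 50, 0.3),
       modelSpec("CGF1", 1, 100, 0.3),
       modelSpec("GA-I", 30, 100, 0.3),
       modelSpec("GA-I", 70, 100, 0.3),
       modelSpec("CGF1-I", 30, 100, 0.3),
       modelSpec("CGF1-I", 70, 100, 0.3))
}

#' Model-determination accuracy study
#'
#' Forward-simulates replicate admixed populations under each scenario of
#' \code{\link{studyScenarios}}, paints SNP panels, computes the jackknife
#' ALD curve set, and runs model selection under both core-model sets (the
#' classic HI/GA/CGF1/CGF2 set and the interval HI/GA-I/CGF1-I/CGF2-I set)
#' on the same curves.  Each selection outcome is classified as correct,
#' undetermined or wrong against the simulated truth (CGF1/CGF2 counted as
#' one CGF class, CGF1-I/CGF2-I as one CGF-I class; an interval core class
#' also matches its boundary non-interval truth).
#'
#' Default problem sizes are desk scale: population 5000, 10 chromosomes of
#' 0.3 Morgan, 1000 sampled haplotypes, 2000 sites per chromosome, source
#' panels of 226 haplotypes at divergence 0.15, onset bound J = 150.
#'
#' @param nRep replicates per scenario (default 10).
#' @param seed base RNG seed; each replicate derives its own sub-seed.
#' @param popSize,nSample,nSites,nSourceHap,bins,J problem sizes.
#' @param scenarios list of \linkS4class{ModelSpec}s (default the ten study
#'   scenarios).
#' @param verbose print one line per replicate.
#' @return data.frame with one row per (scenario, replicate): the truth,
#'   the selected model sets and the outcome classes under both core sets.
#' @export
accuracyStudy <- function(nRep = 10L, seed = 1L, popSize = 5000L,
                          nSample = 1000L, nSites = 2000L,
                          nSourceHap = 226L,
                          bins = binSpec(0.005, 0.3, 0.001), J = 150L,
                          scenarios = studyScenarios(), verbose = FALSE) {
  core1 <- c("HI", "GA", "CGF1", "CGF2")
  core2 <- c("HI", "GA-I", "CGF1-I", "CGF2-I")
  baseSeed <- as.integer(abs(seed) %% 100000L)
  rows <- list()
  for (i in seq_along(scenarios)) {
    spec <- scenarios[[i]]
    for (r in seq_len(nRep)) {
      set.seed(baseSeed * 10000L + i * 100L + r)
      sim <- simulatePanels(spec, popSize = popSize,
                            chromLengths = rep(0.3, 10), nSample = nSample,
                            panelModel = sourcePanelModel(nSites = nSites),
                            nSourceHap = nSourceHap)
      cs <- curveSet(sim$panels$admixed, sim$panels$source1,
                     sim$panels$source2, spec@m1, bins)
      r1 <- selectModels(cs, core1, J = J)
      r2 <- selectModels(cs, core2, J = J)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sprintf("%s(%d-%d)", spec@model, spec@gEnd, spec@gStart),
        truth = spec@model, rep = r,
        best_classic = paste(bestModels(r1), collapse = "+"),
        class_classic = classifySelection(bestModels(r1), spec@model),
        best_interval = paste(bestModels(r2), collapse = "+"),
        class_interval = classifySelection(bestModels(r2), spec@model))
      if (verbose)
        message(sprintf("%s rep %d: classic=%s interval=%s",
                        rows[[length(rows)]]$scenario, r,
                        rows[[length(rows)]]$class_classic,
                        rows[[length(rows)]]$class_interval))
    }
  }
  do.call(rbind, rows)
}

#' Accuracy rates of a study result
#'
#' Tabulates, in percent, the model-determination rates of an
#' \code{\link{accuracyStudy}} result in the four-row layout of the study
#' design: classic truths (HI/GA/CGF) and interval truths (GA-I/CGF-I),
#' each under the classic and the interval core-model sets.
#'
#' @param study the data.frame returned by \code{\link{accuracyStudy}}.
#' @return data.frame with columns truths, cores, correct, undetermined,
#'   wrong (percentages).
#' @export
accuracyRates <- function(study) {
  classic <- study$truth %in% c("HI", "GA", "CGF1", "CGF2")
  pct <- function(cls, what) 100 * mean(cls == what)
  mk <- function(rowsSel, col, truths, cores)
    data.frame(truths = truths, cores = cores,
               correct = pct(study[rowsSel, col], "correct"),
               undetermined = pct(study[rowsSel, col], "undetermined"),
               wrong = pct(study[rowsSel, col], "wrong"))
  rbind(mk(classic, "class_classic", "HI;GA;CGF", "HI;GA;CGF"),
        mk(!classic, "class_classic", "GA-I;CGF-I", "HI;GA;CGF"),
        mk(classic, "class_interval", "HI;GA;CGF", "HI;GA-I;CGF-I"),
        mk(!classic, "class_interval", "GA-I;CGF-I", "HI;GA-I;CGF-I"))
}
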