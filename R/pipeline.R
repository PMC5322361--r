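#' Run the full pipeline: simulate -> ALD -> fit -> select -> report
#'
#' Orchestrates one end-to-end run.  Either simulates panels under
#' `trueSpec` or reads them (`panels` list / `curveFile`), computes the
#' jackknife ALD curve set, fits the requested core models and writes
#' `curves.tsv`, `report.json` (and the simulated `*.haps` + `sites.map`
#' when simulating) into `outDir` with a provenance block.
#'
#' @param outDir output directory.
#' @param trueSpec a \linkS4class{ModelSpec} to simulate (ignored when
#'   `panels` or `curveFile` is given).
#' @param panels optional named list (admixed, source1, source2) of
#'   \linkS4class{HaplotypePanel}s.
#' @param curveFile optional precomputed curve-set TSV.
#' @param m1 admixture proportion (needed with `panels`).
#' @param coreModels core model set for selection.
#' @param J onset upper bound (generations).
#' @param bins a \code{\link{binSpec}}.
#' @param popSize,chromLengths,nSample,panelModel,nSourceHap simulator
#'   settings (see \code{\link{simulatePanels}}).
#' @param seed RNG seed.
#' @param force overwrite an existing output directory.
#' @param writePanels also write the simulated panels and tract table.
#' @return the \linkS4class{SelectionReport}, invisibly.
#' @export
runPipeline <- function(outDir, trueSpec = NULL, panels = NULL,
                        curveFile = NULL, m1 = 0.3,
                        coreModels = c("HI", "GA-I", "CGF1-I", "CGF2-I"),
                        J = 500L, bins = binSpec(),
                        popSize = 5000L, chromLengths = rep(0.3, 10),
                        nSample = 200L, panelModel = sourcePanelModel(),
                        nSourceHap = 226L, seed = NULL, force = FALSE,
                        writePanels = FALSE) {
  if (dir.exists(outDir) && length(list.files(outDir)) && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)", outDir))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)

  tracts <- NULL
  if (!is.null(curveFile)) {
    message("stage curves: reading ", curveFile)
    cs <- readCurveSet(curveFile)
  } else {
    if (is.null(panels)) {
      if (is.null(trueSpec)) stop("stage simulate: need trueSpec, panels or curveFile")
      message(sprintf("stage simulate: %s(%d-%d), pop %d",
                      trueSpec@model, trueSpec@gEnd, trueSpec@gStart, popSize))
      sim <- simulatePanels(trueSpec, popSize, chromLengths, nSample,
                            panelModel, nSourceHap)
      panels <- sim$panels
      tracts <- sim$tracts
      m1 <- trueSpec@m1
      if (writePanels) {
        writePanelSet(panels, outDir)
        utils::write.table(tracts@tracts, file.path(outDir, "tracts.bed"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    message("stage ald: computing jackknife curve set")
    cs <- curveSet(panels$admixed, panels$source1, panels$source2, m1, bins)
    writeCurveSet(cs, file.path(outDir, "curves.tsv"))
  }
  message("stage fit/select: core models ", paste(coreModels, collapse = ", "))
  report <- selectModels(cs, coreModels, J = J)
  prov <- list(package = "camix",
               version = as.character(utils::packageVersion("camix")),
               seed = if (is.null(seed)) NA else seed,
               core_models = coreModels, J = J, m1 = cs@m1,
               config_hash = sum(utils::head(c(J, cs@m1, length(cs@full@d),
                                               cs@full@d), 50)))
  writeReport(report, file.path(outDir, "report.json"), provenance = prov)
  message("best-fit model(s): ", paste(report@bestSet, collapse = ", "))
  invisible(report)
}
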