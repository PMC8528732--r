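## End-to-end pipeline over a scenario directory (toy_json models + media
## TSVs), producing one report directory with the growth grid, the
## flux-ratio matrix, the exchanged-metabolite calls, the supplementation
## screen and the cumulative-flux table.  Stages fail independently:
## completed outputs are kept and the failure is logged to stderr.

#' Run the full analysis pipeline on a scenario directory
#'
#' Loads every \code{*.json} model and \code{*.tsv} medium in
#' \code{scenarioDir} (see [writeFixtures()] for the layout), then runs
#' four stages: (1) the mono/pair growth grid on all media; (2) a
#' co-culture of the first two species on the base medium with the
#' flux-ratio snapshot and exchanged-metabolite calls (skipped with a log
#' note when fewer than two species are present); (3) the
#' single-metabolite supplementation screen for the species with the
#' weakest mono-culture growth on the base medium; (4) the
#' cumulative-flux table comparing the base medium against the screen's
#' top metabolite.  Reports are tab-separated; the configuration echo and
#' seed are written alongside.
#'
#' @param scenarioDir directory of toy_json models and media TSVs.
#' @param outDir report directory (created).
#' @param baseMedium name of the base medium (default \code{"limiting"}
#'   when present, else the first medium alphabetically).
#' @param time flux-ratio snapshot time in h.
#' @param config an [ArenaConfig-class].
#' @param nRuns replicates for the growth grid.
#' @param dose screen dose in mM.
#' @return invisibly, the paths of the report files written.
#' @export
runPipeline <- function(scenarioDir, outDir, baseMedium = NULL, time = 32,
                        config = arenaConfig(), nRuns = 3, dose = 10) {
  modelFiles <- sort(list.files(scenarioDir, "\\.json$", full.names = TRUE))
  mediaFiles <- sort(list.files(scenarioDir, "\\.tsv$", full.names = TRUE))
  if (!length(modelFiles)) stop("no .json models in ", scenarioDir)
  if (!length(mediaFiles)) stop("no .tsv media in ", scenarioDir)
  models <- lapply(modelFiles, readModel)
  names(models) <- vapply(models, speciesId, character(1))
  media <- lapply(mediaFiles, loadMedium)
  names(media) <- vapply(media, mediumName, character(1))
  if (is.null(baseMedium))
    baseMedium <- if ("limiting" %in% names(media)) "limiting" else
      names(media)[1]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(...) message("[pipeline] ", ...)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      note("stage '", name, "' failed: ", conditionMessage(e)))
  }
  tsv <- function(df, f) {
    p <- file.path(outDir, f)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    written <<- c(written, p)
  }

  stage("grid", function() {
    grid <- growthGrid(models, media, config = config, nRuns = nRuns)
    tsv(grid, "grid.tsv")
  })

  inocAll <- setNames(rep(5L, length(models)), names(models))
  if (length(models) >= 2L) {
    stage("crossfeed", function() {
      spA <- names(models)[1]; spB <- names(models)[2]
      co <- runSimulation(models[c(spA, spB)], media[[baseMedium]],
                          inocAll[c(spA, spB)], config)
      snapTime <- if (time <= config@horizon) time else config@horizon
      tsv(ratioMatrix(co, spA, spB, time = snapTime), "ratio_matrix.tsv")
      tsv(detectExchanged(co, spA, spB), "exchanged.tsv")
    })
  } else {
    note("crossfeed stage skipped: fewer than two species")
  }

  screenTop <- NULL
  stage("screen", function() {
    mono <- vapply(names(models), function(sp) {
      res <- runSimulation(models[[sp]], media[[baseMedium]],
                           setNames(5L, sp), config)
      unname(res@biomass[nrow(res@biomass), sp])
    }, numeric(1))
    target <- names(models)[which.min(mono)]
    cands <- unique(c(
      exchangeReactions(models[[target]])$metabolite,
      names(media[[baseMedium]]@components)))
    scr <- supplementationScreen(models[[target]], media[[baseMedium]],
                                 cands, dose = dose, config = config)
    scr <- cbind(species = target, scr)
    tsv(scr, "screen.tsv")
    screenTop <<- list(species = target, metabolite = scr$metabolite[1])
  })

  stage("cumflux", function() {
    if (is.null(screenTop)) stop("screen stage did not complete")
    sp <- screenTop$species
    base <- runSimulation(models[[sp]], media[[baseMedium]],
                          setNames(5L, sp), config)
    supp <- runSimulation(models[[sp]],
                          supplementMedium(media[[baseMedium]],
                                           screenTop$metabolite, dose),
                          setNames(5L, sp), config)
    tsv(cumulativeFluxTable(base, supp, sp), "cumflux.tsv")
  })

  echo <- list(scenarioDir = scenarioDir, baseMedium = baseMedium,
               time = time, nRuns = nRuns, dose = dose,
               seed = config@seed,
               package = as.character(packageVersion("fluxarena")))
  jsonlite::write_json(echo, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}
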