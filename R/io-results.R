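## Tidy TSV writers for simulation results and reports, the config echo
## that makes every output directory re-executable, and the
## deposited-model screen entry point.

#' Write a simulation result as tidy TSV tables
#'
#' Writes \code{biomass.tsv} (time, species, biomass_pg),
#' \code{media.tsv} (time, metabolite, mM), \code{exchanges.tsv}
#' (time, species, reaction, flux) and \code{config.json} (the full
#' configuration echo including the seed and package version, from which
#' the run can be re-executed to identical outputs).
#'
#' @param result a [SimulationResult-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulationResult <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE,
                                     na = "NA")
  bio <- result@biomass
  tsv(data.frame(time = rep(result@times, ncol(bio)),
                 species = rep(colnames(bio), each = nrow(bio)),
                 biomass_pg = as.vector(bio)), "biomass.tsv")
  conc <- result@concentrations
  tsv(data.frame(time = rep(result@times, ncol(conc)),
                 metabolite = rep(colnames(conc), each = nrow(conc)),
                 mM = as.vector(conc)), "media.tsv")
  exch <- do.call(rbind, lapply(names(result@exchange), function(sp) {
    m <- result@exchange[[sp]]
    if (ncol(m) == 0) return(NULL)
    data.frame(time = rep(result@times, ncol(m)),
               species = sp, reaction = rep(colnames(m), each = nrow(m)),
               flux = as.vector(m), stringsAsFactors = FALSE)
  }))
  if (is.null(exch))
    exch <- data.frame(time = numeric(), species = character(),
                       reaction = character(), flux = numeric())
  tsv(exch, "exchanges.tsv")
  jsonlite::write_json(result@configEcho, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a flux-ratio matrix as TSV
#'
#' Not-shared entries are written as \code{NA}.
#'
#' @param mat a [ratioMatrix()] data frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRatioMatrix <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Supplementation screen on deposited genome-scale models
#'
#' Runs [supplementationScreen()] for a model file (SBML or toy_json) on a
#' medium TSV -- the entry point for reproducing the published
#' 43-candidate defined-diet screen with the study's deposited
#' genome-scale models, which must be downloaded separately (they are not
#' shipped with the package).
#'
#' @param modelPath model file (SBML L3/FBC or toy_json).
#' @param mediumPath medium TSV (see [loadMedium()]).
#' @param candidates metabolite ids to test; defaults to every exchange
#'   metabolite of the model that is present in the medium.
#' @param dose dose in mM.
#' @param ... passed to [supplementationScreen()].
#' @return the screen table plus attribute \code{nPromoting}.
#' @export
depositSupplementationScreen <- function(modelPath, mediumPath,
                                         candidates = NULL, dose = 10,
                                         ...) {
  model <- readModel(modelPath)
  medium <- loadMedium(mediumPath)
  if (is.null(candidates)) {
    ex <- exchangeReactions(model)$metabolite
    candidates <- intersect(ex, names(medium@components))
  }
  out <- supplementationScreen(model, medium, candidates, dose = dose, ...)
  attr(out, "nPromoting") <- sum(out$promoting, na.rm = TRUE)
  out
}
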