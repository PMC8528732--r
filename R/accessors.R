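## Accessor generics and show methods.

#' @rdname MetabolicModel-class
#' @param object,x a \code{MetabolicModel}.
#' @export
setGeneric("speciesId", function(object) standardGeneric("speciesId"))

#' @rdname MetabolicModel-class
#' @export
setMethod("speciesId", "MetabolicModel", function(object) object@speciesId)

#' @rdname MetabolicModel-class
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname MetabolicModel-class
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname MetabolicModel-class
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-class
#' @export
setMethod("stoichiometry", "MetabolicModel",
          function(object) object@stoichiometry)

#' @rdname MetabolicModel-class
#' @export
setGeneric("biomassId", function(object) standardGeneric("biomassId"))

#' @rdname MetabolicModel-class
#' @export
setMethod("biomassId", "MetabolicModel", function(object) object@biomassId)

#' Exchange reactions of a model
#'
#' @param model a [MetabolicModel-class].
#' @return \code{data.frame} with columns \code{reaction} and
#'   \code{metabolite} (the single external metabolite each exchange
#'   reaction moves; secretion-positive convention).
#' @export
exchangeReactions <- function(model) {
  rxn <- model@reactions
  ex <- which(rxn$exchange)
  mets <- vapply(ex, function(j) {
    nz <- which(model@stoichiometry[, j] != 0)
    model@metabolites$id[nz[1L]]
  }, character(1))
  data.frame(reaction = rxn$id[ex], metabolite = mets,
             stringsAsFactors = FALSE)
}

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@speciesId, "'\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites (",
      sum(object@metabolites$compartment == "external"), " external), ",
      nrow(object@reactions), " reactions (",
      sum(object@reactions$exchange), " exchange)\n", sep = "")
  cat("  biomass reaction:", object@biomassId, "\n")
})

#' @rdname FluxSolution-class
#' @param object a \code{FluxSolution}.
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname FluxSolution-class
#' @export
setMethod("growthRate", "FluxSolution", function(object) object@growthRate)

#' @rdname FluxSolution-class
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxSolution-class
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname FluxSolution-class
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname FluxSolution-class
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution: status=", object@status,
      ", growth rate mu=", format(object@growthRate, digits = 6),
      " /h, ", length(object@fluxes), " fluxes\n", sep = "")
})

#' @rdname Medium-class
#' @param object,x a \code{Medium}.
#' @export
setGeneric("mediumName", function(object) standardGeneric("mediumName"))

#' @rdname Medium-class
#' @export
setMethod("mediumName", "Medium", function(object) object@name)

#' @rdname Medium-class
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname Medium-class
#' @export
setMethod("components", "Medium", function(object) object@components)

#' @rdname Medium-class
#' @export
setGeneric("replenishedSet", function(object) standardGeneric("replenishedSet"))

#' @rdname Medium-class
#' @export
setMethod("replenishedSet", "Medium", function(object) object@replenished)

setMethod("show", "Medium", function(object) {
  cat("Medium '", object@name, "': ", length(object@components),
      " components, ", length(object@replenished), " replenished\n", sep = "")
})

setMethod("show", "Arena", function(object) {
  cat("Arena ", object@config@rows, "x", object@config@cols, " at t=",
      object@time, " h: ", nrow(object@agents), " agents (",
      format(sum(object@agents$biomass), digits = 6), " pg), ",
      length(object@fields), " substrate fields\n", sep = "")
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult: ", length(object@times), " timepoints (0..",
      max(object@times), " h), species: ",
      paste(colnames(object@biomass), collapse = ", "), "\n", sep = "")
  fin <- object@biomass[nrow(object@biomass), , drop = TRUE]
  cat("  final biomass [pg]: ",
      paste(sprintf("%s=%.2f", names(fin), fin), collapse = ", "), "\n",
      sep = "")
})

#' @rdname SimulationResult-class
#' @param object a \code{SimulationResult}.
#' @export
setGeneric("biomassSeries", function(object) standardGeneric("biomassSeries"))

#' @rdname SimulationResult-class
#' @export
setMethod("biomassSeries", "SimulationResult", function(object) object@biomass)

#' @rdname SimulationResult-class
#' @export
setGeneric("concentrationSeries",
           function(object) standardGeneric("concentrationSeries"))

#' @rdname SimulationResult-class
#' @export
setMethod("concentrationSeries", "SimulationResult",
          function(object) object@concentrations)

#' @rdname SimulationResult-class
#' @export
setGeneric("exchangeSeries", function(object) standardGeneric("exchangeSeries"))

#' @rdname SimulationResult-class
#' @export
setMethod("exchangeSeries", "SimulationResult", function(object) object@exchange)
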