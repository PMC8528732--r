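#' @useDynLib fluxarena, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix colSums
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## MetabolicModel
## ---------------------------------------------------------------------------

#' Constraint-based metabolic model
#'
#' An S4 container for a small constraint-based metabolic network: a
#' metabolite table, a reaction table with flux bounds, a (sparse)
#' stoichiometric matrix and a designated biomass reaction whose flux is the
#' growth rate \eqn{\mu} (h\eqn{^{-1}}).
#'
#' The package-wide sign convention for exchange reactions is
#' \emph{secretion-positive}: an exchange reaction consumes its single
#' external metabolite with stoichiometric coefficient \eqn{-1}, so a
#' positive flux exports the metabolite to the environment and a negative
#' flux is uptake.  Flux units are mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}}
#' throughout.
#'
#' @slot speciesId single species identifier.
#' @slot metabolites \code{data.frame} with columns \code{id}, \code{name},
#'   \code{compartment} (\code{"internal"} or \code{"external"}),
#'   \code{formula} (elemental formula or \code{NA}) and \code{charge}
#'   (integer or \code{NA}).
#' @slot reactions \code{data.frame} with columns \code{id}, \code{lb},
#'   \code{ub} (mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}}), \code{exchange}
#'   (logical) and \code{objective} (objective coefficient).
#' @slot stoichiometry sparse \code{\link[Matrix]{Matrix}}, metabolites in
#'   rows, reactions in columns.
#' @slot biomassId id of the biomass reaction (objective coefficient 1).
#'
#' @seealso [solveFBA()], [readModel()], [makeChainSpecies()]
#' @export
setClass("MetabolicModel",
  representation(
    speciesId     = "character",
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "Matrix",
    biomassId     = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S   <- object@stoichiometry
  if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-empty string")
  if (anyDuplicated(met$id))
    msg <- c(msg, "metabolite ids must be unique")
  if (anyDuplicated(rxn$id))
    msg <- c(msg, "reaction ids must be unique")
  if (!all(met$compartment %in% c("internal", "external")))
    msg <- c(msg, "compartment must be 'internal' or 'external'")
  if (any(rxn$lb > rxn$ub))
    msg <- c(msg, "every reaction must satisfy lb <= ub")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    msg <- c(msg, "stoichiometry dimnames must match metabolite/reaction ids")
  if (nrow(rxn) > 0L && any(Matrix::colSums(S != 0) == 0))
    msg <- c(msg, "stoichiometric matrix has all-zero reaction columns")
  if (!(object@biomassId %in% rxn$id)) {
    msg <- c(msg, sprintf("biomass reaction '%s' not found", object@biomassId))
  } else if (rxn$objective[match(object@biomassId, rxn$id)] != 1) {
    msg <- c(msg, "biomass reaction must have objective coefficient 1")
  }
  ## exchange structure: one external metabolite, coefficient -1;
  ## external metabolites are exactly those referenced by exchange reactions
  if (nrow(rxn) > 0L) {
    exRef <- character()
    for (j in which(rxn$exchange)) {
      coefs <- S[, j]
      nz <- which(coefs != 0)
      if (length(nz) != 1L || coefs[nz] != -1) {
        msg <- c(msg, sprintf(
          "exchange reaction '%s' must have exactly one metabolite with coefficient -1",
          rxn$id[j]))
        next
      }
      exRef <- c(exRef, met$id[nz])
    }
    extIds <- met$id[met$compartment == "external"]
    if (!setequal(extIds, unique(exRef)))
      msg <- c(msg,
        "external metabolites must be exactly those referenced by exchange reactions")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MetabolicModel-class construct a model from its parts and
#'   validate it.  \code{stoich} may be a named list of named numeric
#'   vectors (one per reaction) instead of a matrix.
#' @param speciesId,metabolites,reactions,stoich,biomassId see slots.
#' @export
MetabolicModel <- function(speciesId, metabolites, reactions, stoich,
                           biomassId) {
  metabolites <- normalizeMetaboliteTable(metabolites)
  reactions   <- normalizeReactionTable(reactions)
  if (is.list(stoich) && !is(stoich, "Matrix")) {
    S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoich)) {
      coefs <- stoich[[rid]]
      bad <- setdiff(names(coefs), metabolites$id)
      if (length(bad))
        stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                     rid, paste(bad, collapse = ", ")))
      S[names(coefs), rid] <- unname(coefs)
    }
  } else {
    S <- Matrix::Matrix(stoich, sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }
  new("MetabolicModel", speciesId = speciesId, metabolites = metabolites,
      reactions = reactions, stoichiometry = S, biomassId = biomassId)
}

normalizeMetaboliteTable <- function(met) {
  met <- as.data.frame(met, stringsAsFactors = FALSE)
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$formula)) met$formula <- NA_character_
  if (is.null(met$charge)) met$charge <- NA_integer_
  met$charge <- as.integer(met$charge)
  rownames(met) <- NULL
  met[, c("id", "name", "compartment", "formula", "charge")]
}

normalizeReactionTable <- function(rxn) {
  rxn <- as.data.frame(rxn, stringsAsFactors = FALSE)
  if (is.null(rxn$objective)) rxn$objective <- 0
  rxn$lb <- as.numeric(rxn$lb)
  rxn$ub <- as.numeric(rxn$ub)
  rxn$exchange <- as.logical(rxn$exchange)
  rownames(rxn) <- NULL
  rxn[, c("id", "lb", "ub", "exchange", "objective")]
}

## ---------------------------------------------------------------------------
## FluxSolution
## ---------------------------------------------------------------------------

#' Steady-state flux solution
#'
#' Result of [solveFBA()].  When \code{status == "optimal"} the flux vector
#' satisfies \eqn{S v = 0} and the bounds within solver tolerance, and
#' \code{growthRate} is the biomass reaction flux (h\eqn{^{-1}}).  Infeasible
#' problems carry growth rate 0 and an empty flux vector.
#'
#' @slot status one of \code{"optimal"}, \code{"infeasible"}.
#' @slot growthRate biomass flux \eqn{\mu} in h\eqn{^{-1}}.
#' @slot fluxes named numeric vector, mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}}.
#' @export
setClass("FluxSolution",
  representation(status = "character", growthRate = "numeric",
                 fluxes = "numeric"))

## ---------------------------------------------------------------------------
## Medium
## ---------------------------------------------------------------------------

#' Growth medium
#'
#' A named metabolite-to-concentration table (mM) plus the set of
#' metabolites that are held at constant concentration during simulation
#' (replenished each step, e.g. oxygen in a microaerobic environment).
#'
#' @slot name medium name.
#' @slot components named numeric vector, concentrations in mM.
#' @slot replenished character vector of metabolite ids held constant.
#' @seealso [loadMedium()], [supplementMedium()]
#' @export
setClass("Medium",
  representation(name = "character", components = "numeric",
                 replenished = "character"))

setValidity("Medium", function(object) {
  msg <- character()
  if (any(object@components < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (anyDuplicated(names(object@components)))
    msg <- c(msg, "duplicate metabolite ids in components")
  if (length(setdiff(object@replenished, names(object@components))))
    msg <- c(msg, "replenished set must be a subset of the components")
  if (length(msg)) msg else TRUE
})

#' @describeIn Medium-class constructor.
#' @param name,components,replenished see slots.
#' @export
Medium <- function(name, components, replenished = character()) {
  new("Medium", name = name, components = components,
      replenished = replenished)
}

## ---------------------------------------------------------------------------
## ArenaConfig
## ---------------------------------------------------------------------------

#' Arena configuration
#'
#' Parameters of the spatial simulation.  Units: biomass pg
#' (1 pg = 1e-12 gDW), time h, volume L, flux mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}}.
#' The default geometry is a 20 x 20 grid whose total volume is 1 uL, a
#' total biomass capacity of 750 pg and a per-agent division threshold of
#' capacity / (rows x cols) = 1.875 pg; oxygen is kept at 0.1 mM
#' (microaerobic) by per-step replenishment.
#'
#' @slot rows,cols grid shape.
#' @slot cellVolume volume of one grid cell in L.
#' @slot dt timestep in h.
#' @slot horizon simulated time in h (a multiple of \code{dt}).
#' @slot capacity total biomass cap in pg.
#' @slot divisionThreshold biomass at which an agent divides, pg.
#' @slot initialBiomass biomass of inoculated agents, pg.
#' @slot oxygenId metabolite id used for oxygen.
#' @slot oxygenMM oxygen concentration in mM.
#' @slot oxygenReplenished keep oxygen constant each step?
#' @slot diffusionRate per-step mixing fraction in [0, 1] for all solutes.
#' @slot seed integer RNG seed.
#' @export
setClass("ArenaConfig",
  representation(rows = "integer", cols = "integer", cellVolume = "numeric",
                 dt = "numeric", horizon = "numeric", capacity = "numeric",
                 divisionThreshold = "numeric", initialBiomass = "numeric",
                 oxygenId = "character", oxygenMM = "numeric",
                 oxygenReplenished = "logical", diffusionRate = "numeric",
                 seed = "integer"))

setValidity("ArenaConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  steps <- object@horizon / object@dt
  if (abs(steps - round(steps)) > 1e-9)
    msg <- c(msg, "horizon must be a multiple of dt")
  if (object@rows < 1L || object@cols < 1L) msg <- c(msg, "grid must be >= 1x1")
  if (object@capacity <= 0 || object@divisionThreshold <= 0 ||
      object@initialBiomass <= 0 || object@cellVolume <= 0)
    msg <- c(msg, "capacity, thresholds and cellVolume must be positive")
  if (object@diffusionRate < 0 || object@diffusionRate > 1)
    msg <- c(msg, "diffusionRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Build an arena configuration
#'
#' Missing geometry-derived fields are filled in from the documented
#' derivations: \code{cellVolume = totalVolume / (rows*cols)},
#' \code{divisionThreshold = capacity / (rows*cols)} and
#' \code{initialBiomass = divisionThreshold / 2}; all are overridable.
#'
#' @param rows,cols grid shape (default 20 x 20).
#' @param totalVolume total arena volume in L (default 1e-6, i.e. 1 uL).
#' @param cellVolume per-cell volume in L; overrides \code{totalVolume}.
#' @param dt timestep in h.
#' @param horizon simulated time in h.
#' @param capacity total biomass cap in pg.
#' @param divisionThreshold,initialBiomass pg; derived when \code{NULL}.
#' @param oxygenId,oxygenMM,oxygenReplenished microaerobic oxygen setting.
#' @param diffusionRate per-step mixing fraction.
#' @param seed integer RNG seed.
#' @return an [ArenaConfig-class] object.
#' @examples
#' cfg <- arenaConfig(rows = 10, cols = 10, horizon = 20, seed = 1)
#' cfg@divisionThreshold  # 750 / 100
#' @export
arenaConfig <- function(rows = 20L, cols = 20L, totalVolume = 1e-6,
                        cellVolume = NULL, dt = 1, horizon = 45,
                        capacity = 750, divisionThreshold = NULL,
                        initialBiomass = NULL, oxygenId = "cpd_o2",
                        oxygenMM = 0.1, oxygenReplenished = TRUE,
                        diffusionRate = 0.5, seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.null(cellVolume)) cellVolume <- totalVolume / (rows * cols)
  if (is.null(divisionThreshold)) divisionThreshold <- capacity / (rows * cols)
  if (is.null(initialBiomass)) initialBiomass <- divisionThreshold / 2
  new("ArenaConfig", rows = rows, cols = cols, cellVolume = cellVolume,
      dt = dt, horizon = horizon, capacity = capacity,
      divisionThreshold = divisionThreshold, initialBiomass = initialBiomass,
      oxygenId = oxygenId, oxygenMM = oxygenMM,
      oxygenReplenished = oxygenReplenished, diffusionRate = diffusionRate,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Arena
## ---------------------------------------------------------------------------

#' Spatial simulation arena
#'
#' Mutable-style state of one agent-based dynamic-FBA simulation: the agent
#' population, one substrate field (grid of per-cell amounts in fmol) per
#' tracked metabolite, and the captured RNG state so that stepping is
#' reproducible and pure (functions return an updated copy).
#'
#' @slot models named list of [MetabolicModel-class] objects.
#' @slot config an [ArenaConfig-class].
#' @slot agents \code{data.frame}: \code{id}, \code{species}, \code{biomass}
#'   (pg), \code{row}, \code{col}.
#' @slot fields named list of \code{rows x cols} matrices, amounts in fmol.
#' @slot fieldInfo \code{data.frame}: \code{metabolite}, \code{initConc}
#'   (mM), \code{replenished}.
#' @slot occupied integer matrix of agent ids (0 = free).
#' @slot time current simulated time in h.
#' @slot nextId next agent id.
#' @slot rngState captured \code{.Random.seed}.
#' @seealso [initArena()], [stepArena()], [runSimulation()]
#' @export
setClass("Arena",
  representation(models = "list", config = "ArenaConfig", agents = "data.frame",
                 fields = "list", fieldInfo = "data.frame",
                 occupied = "matrix", time = "numeric", nextId = "integer",
                 rngState = "ANY"))

## ---------------------------------------------------------------------------
## SimulationResult
## ---------------------------------------------------------------------------

#' Time series of one (or averaged) arena simulation
#'
#' @slot times time grid in h (t = 0 is the initial state).
#' @slot biomass matrix time x species, total biomass in pg.
#' @slot concentrations matrix time x metabolite, arena-mean concentration
#'   in mM.
#' @slot exchange named list, one \code{time x reaction} matrix per species
#'   with the biomass-weighted mean exchange flux
#'   (mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}}; secretion positive) realised in the
#'   step ending at each time (0 at t = 0).
#' @slot exchangeMap \code{data.frame}: \code{species}, \code{reaction},
#'   \code{metabolite} for every exchange reaction.
#' @slot seed RNG seed used (NA for replicate means).
#' @slot configEcho list echo of the configuration.
#' @seealso [runSimulation()], [productionCurve()], [ratioMatrix()]
#' @export
setClass("SimulationResult",
  representation(times = "numeric", biomass = "matrix",
                 concentrations = "matrix", exchange = "list",
                 exchangeMap = "data.frame", seed = "integer",
                 configEcho = "list"))

setValidity("SimulationResult", function(object) {
  msg <- character()
  nT <- length(object@times)
  if (nrow(object@biomass) != nT || nrow(object@concentrations) != nT)
    msg <- c(msg, "series lengths must equal the time grid")
  if (any(object@biomass < 0)) msg <- c(msg, "biomass series must be >= 0")
  if (length(msg)) msg else TRUE
})
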