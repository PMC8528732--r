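# Shared fixtures for the test suite.  Grids are kept small (total arena
# volume stays 1 uL, so medium amounts are geometry-independent).

smallCfg <- function(rows = 10, cols = 10, horizon = 20, seed = 1, ...) {
  arenaConfig(rows = rows, cols = cols, horizon = horizon, seed = seed, ...)
}

quietSim <- function(...) suppressWarnings(runSimulation(...))
quietReps <- function(...) suppressWarnings(runReplicates(...))

finalBiomass <- function(result, species = NULL) {
  fin <- biomassSeries(result)[length(result@times), ]
  if (is.null(species)) fin else unname(fin[species])
}

# ad-hoc model builder for solver edge cases
adhocModel <- function(speciesId, mets, rxns, stoich, biomass = "BIOMASS") {
  MetabolicModel(speciesId, mets, rxns, stoich, biomass)
}

met <- function(id, compartment = "internal", formula = NA, charge = NA) {
  data.frame(id = id, name = id, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

rxnrow <- function(id, lb, ub, exchange = FALSE, objective = 0) {
  data.frame(id = id, lb = lb, ub = ub, exchange = exchange,
             objective = objective, stringsAsFactors = FALSE)
}
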