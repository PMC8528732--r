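## Agent-based dynamic FBA on a spatial grid.
##
## Each step, in a freshly shuffled agent order: uptake bounds are tightened
## to the locally available amounts, FBA is solved, biomass grows by
## exp(mu * dt) (truncated at twice the division threshold and clipped to
## the remaining arena capacity), local substrate amounts change by
## v_ex * biomass * dt (secretion positive), agents above the division
## threshold split onto a free von Neumann neighbour cell (deferred when
## none is free), substrate fields mix diffusively with closed boundaries,
## and replenished fields (oxygen) are reset to their initial concentration.
##
## Unit bookkeeping: amounts are stored in fmol per cell.  With biomass in
## pg (1 pg = 1e-12 gDW) and fluxes in mmol/gDW/h, the per-step amount
## change is numerically v * biomass_pg * dt fmol, and the availability
## bound is amount_fmol / (biomass_pg * dt) mmol/gDW/h.

.mMToFmol <- function(mM, cellVolume) mM * cellVolume * 1e12
.fmolToMM <- function(fmol, cellVolume) fmol / (cellVolume * 1e12)

#' Initialise a simulation arena
#'
#' Agents are placed uniformly at random (seeded from the config) on
#' distinct grid cells with the configured initial biomass.  One substrate
#' field is created for every medium component and every exchange
#' metabolite of any model (so that secreted products are tracked even
#' when absent from the medium); each concentration c (mM) becomes a
#' per-cell amount c x cellVolume, distributed uniformly.  Oxygen is added
#' at \code{config@oxygenMM} (replenished each step by default) unless the
#' medium already specifies it.
#'
#' @param models list of [MetabolicModel-class] objects (distinct species).
#' @param medium a [Medium-class].
#' @param inoculum named integer vector, species id -> agent count.
#' @param config an [ArenaConfig-class].
#' @return an [Arena-class].
#' @export
initArena <- function(models, medium, inoculum, config = arenaConfig()) {
  if (is(models, "MetabolicModel")) models <- list(models)
  ids <- vapply(models, speciesId, character(1))
  if (anyDuplicated(ids)) stop("species ids must be distinct")
  names(models) <- ids
  inoculum <- inoculum[inoculum > 0]
  storage.mode(inoculum) <- "integer"
  bad <- setdiff(names(inoculum), ids)
  if (length(bad)) stop("inoculum names unknown: ", paste(bad, collapse = ", "))
  nCells <- config@rows * config@cols
  if (sum(inoculum) > nCells)
    stop(sprintf("inoculum (%d agents) exceeds the %d grid cells",
                 sum(inoculum), nCells))

  exMets <- unique(unlist(lapply(models,
                                 function(m) exchangeReactions(m)$metabolite)))
  comp <- medium@components
  orphan <- setdiff(names(comp), exMets)
  if (length(orphan))
    warning("medium metabolite(s) absent from every model (still tracked): ",
            paste(orphan, collapse = ", "))
  trackIds <- union(names(comp), exMets)
  initConc <- setNames(rep(0, length(trackIds)), trackIds)
  initConc[names(comp)] <- comp
  repl <- trackIds %in% medium@replenished
  names(repl) <- trackIds
  if (config@oxygenMM > 0 && !(config@oxygenId %in% names(comp))) {
    if (!(config@oxygenId %in% trackIds)) {
      trackIds <- c(trackIds, config@oxygenId)
      initConc <- c(initConc, setNames(config@oxygenMM, config@oxygenId))
      repl <- c(repl, setNames(config@oxygenReplenished, config@oxygenId))
    } else {
      initConc[config@oxygenId] <- config@oxygenMM
      repl[config@oxygenId] <- config@oxygenReplenished
    }
  }

  fields <- lapply(initConc, function(cc)
    matrix(.mMToFmol(cc, config@cellVolume), config@rows, config@cols))
  names(fields) <- trackIds
  fieldInfo <- data.frame(metabolite = trackIds,
                          initConc = unname(initConc),
                          replenished = unname(repl),
                          stringsAsFactors = FALSE)

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(config@seed)
  occupied <- matrix(0L, config@rows, config@cols)
  agents <- data.frame(id = integer(), species = character(),
                       biomass = numeric(), row = integer(), col = integer(),
                       stringsAsFactors = FALSE)
  nextId <- 1L
  for (sp in names(inoculum)) {
    free <- which(occupied == 0L)
    cells <- free[sample.int(length(free), inoculum[[sp]])]
    rows <- (cells - 1L) %% config@rows + 1L
    cols <- (cells - 1L) %/% config@rows + 1L
    idsNew <- seq.int(nextId, length.out = inoculum[[sp]])
    occupied[cells] <- idsNew
    agents <- rbind(agents, data.frame(
      id = idsNew, species = sp,
      biomass = config@initialBiomass, row = rows, col = cols,
      stringsAsFactors = FALSE))
    nextId <- nextId + inoculum[[sp]]
  }
  rngState <- get(".Random.seed", globalenv())

  new("Arena", models = models, config = config, agents = agents,
      fields = fields, fieldInfo = fieldInfo, occupied = occupied,
      time = 0, nextId = nextId, rngState = rngState)
}

## Per-species solver-ready cache
.buildCache <- function(models) {
  lapply(models, function(m) {
    ex <- exchangeReactions(m)
    rxn <- m@reactions
    list(A = as.matrix(m@stoichiometry), b = rep(0, nrow(m@metabolites)),
         lb = rxn$lb, ub = rxn$ub, obj = rxn$objective,
         rxnIds = rxn$id,
         biomassIdx = match(m@biomassId, rxn$id),
         exIdx = match(ex$reaction, rxn$id), exMet = ex$metabolite)
  })
}

## closed-boundary von Neumann diffusion; exact conservation
.neighborCounts <- function(nr, nc) {
  K <- matrix(4L, nr, nc)
  K[1, ] <- K[1, ] - 1L; K[nr, ] <- K[nr, ] - 1L
  K[, 1] <- K[, 1] - 1L; K[, nc] <- K[, nc] - 1L
  K
}

.diffuse <- function(mat, d, K) {
  if (d <= 0) return(mat)
  out <- d * mat
  share <- out / K
  nr <- nrow(mat); nc <- ncol(mat)
  inflow <- matrix(0, nr, nc)
  if (nr > 1) {
    inflow[-nr, ] <- inflow[-nr, ] + share[-1, ]   # from below
    inflow[-1, ]  <- inflow[-1, ]  + share[-nr, ]  # from above
  }
  if (nc > 1) {
    inflow[, -nc] <- inflow[, -nc] + share[, -1]   # from right
    inflow[, -1]  <- inflow[, -1]  + share[, -nc]  # from left
  }
  mat - out + inflow
}

## One timestep on the unpacked state; returns the state plus the step's
## population-level exchange-flux accounting used by the recorders.
.stepImpl <- function(st) {
  cfg <- st$cfg
  n <- length(st$biomass)
  ord <- if (n > 0) sample.int(n) else integer()
  sumFlux <- lapply(st$cache, function(cc) numeric(length(cc$exIdx)))
  sumMass <- setNames(numeric(length(st$cache)), names(st$cache))
  total <- sum(st$biomass)

  for (i in ord) {
    sp <- st$species[i]
    cc <- st$cache[[sp]]
    m <- st$biomass[i]
    r <- st$row[i]; cl <- st$col[i]
    lbEff <- cc$lb
    for (k in seq_along(cc$exIdx)) {
      j <- cc$exIdx[k]
      avail <- st$fields[[cc$exMet[k]]][r, cl]
      cap <- -avail / (m * cfg@dt)
      if (lbEff[j] < cap) lbEff[j] <- min(cap, cc$ub[j])
    }
    sol <- lpSolveDense(cc$A, cc$b, cc$obj, lbEff, cc$ub)
    sumMass[sp] <- sumMass[sp] + m
    if (sol$status != 0L) next        # infeasible: no growth, no exchange
    v <- sol$x
    mu <- max(0, v[cc$biomassIdx])
    newm <- min(m * exp(mu * cfg@dt), 2 * cfg@divisionThreshold)
    gain <- newm - m
    headroom <- max(0, cfg@capacity - total)
    scale <- 1
    if (gain > headroom) {
      scale <- if (gain > 0) headroom / gain else 1
      newm <- m + headroom
      gain <- headroom
    }
    for (k in seq_along(cc$exIdx)) {
      dA <- v[cc$exIdx[k]] * scale * m * cfg@dt
      if (dA == 0) next
      met <- cc$exMet[k]
      cur <- st$fields[[met]][r, cl] + dA
      if (cur < 0) cur <- max(cur, 0)  # roundoff guard; bound rules out more
      st$fields[[met]][r, cl] <- cur
      sumFlux[[sp]][k] <- sumFlux[[sp]][k] + v[cc$exIdx[k]] * scale * m
    }
    st$biomass[i] <- newm
    total <- total + gain
    if (newm >= cfg@divisionThreshold) {
      nbr <- rbind(c(r - 1L, cl), c(r + 1L, cl), c(r, cl - 1L), c(r, cl + 1L))
      ok <- nbr[, 1] >= 1L & nbr[, 1] <= cfg@rows &
            nbr[, 2] >= 1L & nbr[, 2] <= cfg@cols
      nbr <- nbr[ok, , drop = FALSE]
      free <- which(st$occupied[nbr] == 0L)
      if (length(free)) {                      # else: division deferred
        pick <- nbr[free[sample.int(length(free), 1L)], ]
        half <- newm / 2
        st$biomass[i] <- half
        st$id <- c(st$id, st$nextId)
        st$species <- c(st$species, sp)
        st$biomass <- c(st$biomass, half)
        st$row <- c(st$row, pick[1]); st$col <- c(st$col, pick[2])
        st$occupied[pick[1], pick[2]] <- st$nextId
        st$nextId <- st$nextId + 1L
      }
    }
  }

  for (f in seq_along(st$fields)) {
    if (st$replenished[f]) {
      st$fields[[f]][] <- .mMToFmol(st$initConc[f], cfg@cellVolume)
    } else {
      st$fields[[f]] <- .diffuse(st$fields[[f]], cfg@diffusionRate, st$K)
    }
  }
  st$time <- st$time + cfg@dt
  st$stepFlux <- sumFlux
  st$stepMass <- sumMass
  st
}

.unpackArena <- function(arena) {
  cfg <- arena@config
  list(cfg = cfg, cache = .buildCache(arena@models),
       id = arena@agents$id, species = arena@agents$species,
       biomass = arena@agents$biomass,
       row = arena@agents$row, col = arena@agents$col,
       occupied = arena@occupied, fields = arena@fields,
       initConc = setNames(arena@fieldInfo$initConc,
                           arena@fieldInfo$metabolite),
       replenished = arena@fieldInfo$replenished,
       K = .neighborCounts(cfg@rows, cfg@cols),
       time = arena@time, nextId = arena@nextId)
}

.repackArena <- function(arena, st) {
  arena@agents <- data.frame(id = st$id, species = st$species,
                             biomass = st$biomass, row = st$row,
                             col = st$col, stringsAsFactors = FALSE)
  arena@fields <- st$fields
  arena@occupied <- st$occupied
  arena@time <- st$time
  arena@nextId <- st$nextId
  arena
}

#' Advance an arena by one timestep
#'
#' @param arena an [Arena-class].
#' @return the arena advanced by \code{dt}, with the captured RNG state so
#'   repeated stepping reproduces [runSimulation()] exactly.
#' @export
stepArena <- function(arena) {
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  assign(".Random.seed", arena@rngState, globalenv())
  st <- .stepImpl(.unpackArena(arena))
  arena <- .repackArena(arena, st)
  arena@rngState <- get(".Random.seed", globalenv())
  arena
}

#' Run a full arena simulation
#'
#' Runs \code{horizon/dt} steps from a fresh arena, recording total
#' biomass per species, arena-mean concentrations and biomass-weighted
#' mean exchange fluxes at every timepoint.  A fixed seed gives a
#' bitwise-identical result.
#'
#' @inheritParams initArena
#' @return a [SimulationResult-class].
#' @examples
#' pair <- makeCompetitorPair()
#' cfg <- arenaConfig(rows = 8, cols = 8, horizon = 10, seed = 1)
#' res <- runSimulation(pair, makeMediaSuite()$rich,
#'                      c(competitor_1 = 2, competitor_2 = 2), cfg)
#' res
#' @export
runSimulation <- function(models, medium, inoculum, config = arenaConfig()) {
  arena <- initArena(models, medium, inoculum, config)
  cfg <- arena@config
  nSteps <- round(cfg@horizon / cfg@dt)
  spIds <- names(arena@models)
  mets <- arena@fieldInfo$metabolite
  exMap <- do.call(rbind, lapply(spIds, function(sp) {
    ex <- exchangeReactions(arena@models[[sp]])
    if (nrow(ex) == 0) return(NULL)
    data.frame(species = sp, reaction = ex$reaction,
               metabolite = ex$metabolite, stringsAsFactors = FALSE)
  }))
  if (is.null(exMap))
    exMap <- data.frame(species = character(), reaction = character(),
                        metabolite = character(), stringsAsFactors = FALSE)

  times <- seq(0, cfg@horizon, by = cfg@dt)
  bioM <- matrix(0, nSteps + 1L, length(spIds),
                 dimnames = list(NULL, spIds))
  conM <- matrix(0, nSteps + 1L, length(mets), dimnames = list(NULL, mets))
  exch <- lapply(spIds, function(sp) {
    rids <- exMap$reaction[exMap$species == sp]
    matrix(0, nSteps + 1L, length(rids), dimnames = list(NULL, rids))
  })
  names(exch) <- spIds

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  assign(".Random.seed", arena@rngState, globalenv())
  st <- .unpackArena(arena)

  record <- function(t) {
    for (sp in spIds)
      bioM[t, sp] <<- sum(st$biomass[st$species == sp])
    conM[t, ] <<- vapply(st$fields[mets], function(f)
      .fmolToMM(mean(f), cfg@cellVolume), numeric(1))
  }
  record(1L)
  for (s in seq_len(nSteps)) {
    st <- .stepImpl(st)
    record(s + 1L)
    for (sp in spIds) {
      w <- st$stepMass[[sp]]
      if (w > 0) exch[[sp]][s + 1L, ] <- st$stepFlux[[sp]] / w
    }
  }

  echo <- list(rows = cfg@rows, cols = cfg@cols, cellVolume = cfg@cellVolume,
               dt = cfg@dt, horizon = cfg@horizon, capacity = cfg@capacity,
               divisionThreshold = cfg@divisionThreshold,
               initialBiomass = cfg@initialBiomass,
               oxygenId = cfg@oxygenId, oxygenMM = cfg@oxygenMM,
               oxygenReplenished = cfg@oxygenReplenished,
               diffusionRate = cfg@diffusionRate, seed = cfg@seed,
               medium = medium@name,
               inoculum = as.list(inoculum),
               package = as.character(packageVersion("fluxarena")))
  new("SimulationResult", times = times, biomass = bioM,
      concentrations = conM, exchange = exch, exchangeMap = exMap,
      seed = cfg@seed, configEcho = echo)
}

#' Run replicate simulations and average them
#'
#' Runs \code{nRuns} independent simulations with seeds
#' \code{baseSeed .. baseSeed + nRuns - 1} and returns the per-timepoint
#' mean series together with the individual runs.  Growth-curve reporting
#' uses 12 replicates by default; metabolite-production profiling
#' conventionally uses \code{nRuns = 100}.
#'
#' @inheritParams initArena
#' @param nRuns number of replicates (>= 1).
#' @param baseSeed seed of the first replicate; defaults to the config seed.
#' @return list with elements \code{mean} (a [SimulationResult-class] with
#'   averaged series, \code{seed = NA}) and \code{runs} (list of per-run
#'   results).
#' @export
runReplicates <- function(models, medium, inoculum, config = arenaConfig(),
                          nRuns = 12, baseSeed = config@seed) {
  stopifnot(nRuns >= 1)
  runs <- vector("list", nRuns)
  for (k in seq_len(nRuns)) {
    cfg <- config
    cfg@seed <- as.integer(baseSeed + k - 1)
    runs[[k]] <- runSimulation(models, medium, inoculum, cfg)
  }
  avg <- runs[[1]]
  if (nRuns > 1) {
    for (k in 2:nRuns) {
      avg@biomass <- avg@biomass + runs[[k]]@biomass
      avg@concentrations <- avg@concentrations + runs[[k]]@concentrations
      for (sp in names(avg@exchange))
        avg@exchange[[sp]] <- avg@exchange[[sp]] + runs[[k]]@exchange[[sp]]
    }
    avg@biomass <- avg@biomass / nRuns
    avg@concentrations <- avg@concentrations / nRuns
    avg@exchange <- lapply(avg@exchange, function(x) x / nRuns)
  }
  avg@seed <- NA_integer_
  avg@configEcho$seed <- NA
  avg@configEcho$nRuns <- nRuns
  avg@configEcho$baseSeed <- baseSeed
  list(mean = avg, runs = runs)
}

#' Arena-total production curve of one metabolite
#'
#' Cumulative net amount of a tracked metabolite over time (arena total),
#' from the recorded arena-mean concentration series.  Negative net change
#' reads as consumption.
#'
#' @param result a [SimulationResult-class].
#' @param metaboliteId tracked metabolite id.
#' @return \code{data.frame} with \code{time} (h), \code{mM} (arena mean),
#'   \code{amount} (total fmol) and \code{net} (fmol change since t = 0).
#' @export
productionCurve <- function(result, metaboliteId) {
  conc <- result@concentrations
  if (!(metaboliteId %in% colnames(conc)))
    stop("metabolite not tracked: ", metaboliteId, " (tracked: ",
         paste(colnames(conc), collapse = ", "), ")")
  echo <- result@configEcho
  nCells <- echo$rows * echo$cols
  amt <- .mMToFmol(conc[, metaboliteId], echo$cellVolume) * nCells
  data.frame(time = result@times, mM = conc[, metaboliteId],
             amount = amt, net = amt - amt[1])
}
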