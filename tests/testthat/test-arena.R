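test_that("medium concentrations convert to per-cell amounts exactly", {
  cfg <- arenaConfig(rows = 10, cols = 10, cellVolume = 1e-9, horizon = 5,
                     oxygenMM = 0, seed = 1)
  med <- Medium("one", c(cpd_glc = 1))
  arena <- suppressWarnings(initArena(list(makeChainSpecies("toy")), med,
                                      c(toy = 1), cfg))
  # 1 mM x 1e-9 L = 1e-9 mmol = 1000 fmol per cell, uniform
  expect_equal(unique(as.vector(arena@fields$cpd_glc)), 1000,
               tolerance = 1e-12)
})

test_that("inoculation is seeded, collision-free and bounded by the grid", {
  cfg <- smallCfg(rows = 4, cols = 4, horizon = 5)
  m <- makeChainSpecies("toy")
  med <- makeMediaSuite()$rich
  a1 <- suppressWarnings(initArena(list(m), med, c(toy = 10), cfg))
  a2 <- suppressWarnings(initArena(list(m), med, c(toy = 10), cfg))
  expect_identical(a1@agents, a2@agents)            # same seed, same layout
  expect_false(any(duplicated(a1@agents[, c("row", "col")])))
  expect_error(suppressWarnings(
    initArena(list(m), med, c(toy = 17), cfg)), "exceeds")
  a0 <- suppressWarnings(initArena(list(m), med,
                                   setNames(integer(), character()), cfg))
  expect_equal(nrow(a0@agents), 0)
})

test_that("stepping an empty arena only mixes: all totals are conserved", {
  cfg <- smallCfg(rows = 6, cols = 6, horizon = 5, oxygenMM = 0)
  med <- Medium("m", c(cpd_glc = 2, cpd_S2 = 1))
  arena <- suppressWarnings(initArena(list(makeChainSpecies("toy")), med,
                                      setNames(integer(), character()), cfg))
  # make one field spatially uneven so diffusion actually moves mass
  arena@fields$cpd_glc[1, 1] <- arena@fields$cpd_glc[1, 1] + 500
  tot0 <- vapply(arena@fields, sum, numeric(1))
  stepped <- stepArena(stepArena(arena))
  tot1 <- vapply(stepped@fields, sum, numeric(1))
  expect_equal(tot1, tot0, tolerance = 1e-12)
  expect_true(all(vapply(stepped@fields, function(f) all(f >= 0),
                         logical(1))))
})

test_that("an agent on exhausted medium neither grows nor exchanges", {
  cfg <- smallCfg(rows = 4, cols = 4, horizon = 6, oxygenMM = 0)
  med <- Medium("empty", c(cpd_glc = 0))
  res <- quietSim(makeChainSpecies("toy"), med, c(toy = 1), cfg)
  bio <- biomassSeries(res)[, "toy"]
  expect_true(all(bio == bio[1]))
  expect_true(all(exchangeSeries(res)$toy == 0))
})

test_that("with abundant substrate biomass follows exp(mu t) exactly", {
  cfg <- arenaConfig(rows = 5, cols = 5, horizon = 6, dt = 1, seed = 2,
                     capacity = 1e9, divisionThreshold = 1e6,
                     initialBiomass = 1)
  res <- quietSim(makeChainSpecies("toy"), makeMediaSuite()$rich,
                  c(toy = 1), cfg)
  bio <- biomassSeries(res)[, "toy"]
  expect_equal(bio, exp(1 * (0:6)), tolerance = 1e-9)
})

test_that("per-step metabolite accounting closes against the flux series", {
  cfg <- smallCfg(rows = 6, cols = 6, horizon = 12, seed = 4)
  res <- quietSim(makeHeterolacticSpecies(), makeMediaSuite()$rich,
                  c(heterolactic = 3), cfg)
  echo <- res@configEcho
  nCells <- echo$rows * echo$cols
  toFmol <- function(mM) mM * echo$cellVolume * 1e12 * nCells
  exch <- exchangeSeries(res)$heterolactic
  map <- res@exchangeMap
  bio <- biomassSeries(res)[, "heterolactic"]
  for (metId in c("cpd_glc", "cpd_lac", "cpd_ac")) {
    amt <- toFmol(concentrationSeries(res)[, metId])
    rid <- map$reaction[map$metabolite == metId]
    for (s in seq_len(length(res@times) - 1)) {
      dExpect <- unname(exch[s + 1, rid]) * bio[s] * echo$dt
      dGot <- amt[s + 1] - amt[s]
      expect_equal(dGot, dExpect,
                   tolerance = 1e-9 * max(1, abs(dExpect)))
    }
    expect_true(all(amt >= 0))
  }
})

test_that("fixed seeds give bitwise-identical results, new seeds differ", {
  pair <- makeCompetitorPair()
  med <- makeMediaSuite()$rich
  inoc <- c(competitor_1 = 3, competitor_2 = 3)
  cfg <- smallCfg(horizon = 15, seed = 7)
  r1 <- quietSim(pair, med, inoc, cfg)
  r2 <- quietSim(pair, med, inoc, cfg)
  expect_identical(biomassSeries(r1), biomassSeries(r2))
  expect_identical(concentrationSeries(r1), concentrationSeries(r2))
  expect_identical(exchangeSeries(r1), exchangeSeries(r2))
  r3 <- quietSim(pair, med, inoc, smallCfg(horizon = 15, seed = 8))
  expect_false(identical(biomassSeries(r1), biomassSeries(r3)))
})

test_that("stepArena reproduces runSimulation step by step", {
  cfg <- smallCfg(rows = 5, cols = 5, horizon = 4, seed = 11)
  m <- makeHeterolacticSpecies()
  med <- makeMediaSuite()$rich
  res <- quietSim(m, med, c(heterolactic = 2), cfg)
  arena <- suppressWarnings(initArena(list(m), med, c(heterolactic = 2), cfg))
  for (s in 1:4) arena <- stepArena(arena)
  expect_equal(sum(arena@agents$biomass),
               unname(biomassSeries(res)[5, "heterolactic"]))
  expect_equal(arena@time, 4)
})

test_that("total biomass never exceeds the capacity and saturates there", {
  pair <- makeCompetitorPair()
  cfg <- smallCfg(horizon = 25, seed = 5)
  res <- quietSim(pair, makeMediaSuite()$rich,
                  c(competitor_1 = 3, competitor_2 = 3), cfg)
  tot <- rowSums(biomassSeries(res))
  expect_true(all(tot <= cfg@capacity + 1e-9))
  expect_equal(tot[length(tot)], cfg@capacity, tolerance = 1e-9)
})

test_that("identical competitors split the arena evenly over 12 seeds", {
  pair <- makeCompetitorPair()
  med <- makeMediaSuite()$rich
  cfg <- smallCfg(horizon = 25, seed = 1)
  reps <- quietReps(pair, med, c(competitor_1 = 3, competitor_2 = 3), cfg,
                    nRuns = 12)
  fin <- biomassSeries(reps$mean)[26, ]
  expect_equal(sum(fin), cfg@capacity, tolerance = 0.05 * cfg@capacity)
  share <- fin[1] / sum(fin)
  expect_gt(share, 0.4); expect_lt(share, 0.6)
  shares <- vapply(reps$runs, function(r)
    finalBiomass(r, "competitor_1") / sum(finalBiomass(r)), numeric(1))
  expect_gt(stats::var(shares), 0)   # stochastic, not frozen
})

test_that("producer rescues the auxotrophic consumer at least five-fold", {
  sc <- makeCrossfeedingPair()
  suite <- makeMediaSuite()
  cfg <- smallCfg(horizon = 45, seed = 2)
  mono <- quietSim(sc$consumer, suite$limiting, c(consumer = 5), cfg)
  co <- quietSim(list(sc$producer, sc$consumer), suite$limiting,
                 c(producer = 5, consumer = 5), cfg)
  expect_equal(finalBiomass(mono, "consumer"),
               unname(biomassSeries(mono)[1, "consumer"]))  # flat: designed auxotrophy
  expect_gte(finalBiomass(co, "consumer"),
             5 * finalBiomass(mono, "consumer"))
})

test_that("replicate means: n = 1 is the run itself; deterministic setups
           have zero variance; oxygen stays clamped", {
  m <- makeChainSpecies("toy")
  med <- makeMediaSuite()$rich
  cfg <- arenaConfig(rows = 5, cols = 5, horizon = 6, seed = 3,
                     capacity = 1e9, divisionThreshold = 1e6,
                     initialBiomass = 1)
  one <- quietReps(m, med, c(toy = 1), cfg, nRuns = 1)
  expect_identical(biomassSeries(one$mean), biomassSeries(one$runs[[1]]))
  reps <- quietReps(m, med, c(toy = 1), cfg, nRuns = 6)
  bios <- vapply(reps$runs, function(r) biomassSeries(r)[, "toy"],
                 numeric(7))
  expect_true(all(apply(bios, 1, function(x) max(x) - min(x)) == 0))
  # replenished oxygen is constant at the configured concentration
  o2 <- concentrationSeries(reps$runs[[1]])[, "cpd_o2"]
  expect_true(all(o2 == 0.1))
})

test_that("production curves report designed secretion and inert tracers", {
  cfg <- smallCfg(rows = 6, cols = 6, horizon = 15, seed = 6)
  res <- quietSim(makeHeterolacticSpecies(), makeMediaSuite()$rich,
                  c(heterolactic = 3), cfg)
  lac <- productionCurve(res, "cpd_lac")
  expect_true(all(diff(lac$amount) >= -1e-9))      # secretion-only design
  expect_gt(lac$net[nrow(lac)], 0)
  s2 <- productionCurve(res, "cpd_S2")             # untouched by the model
  expect_equal(max(abs(s2$net)), 0, tolerance = 1e-9)
  expect_error(productionCurve(res, "cpd_nope"), "not tracked")
  # endpoint re-accounting from the exchange series
  map <- res@exchangeMap
  rid <- map$reaction[map$metabolite == "cpd_lac"]
  bio <- biomassSeries(res)[, "heterolactic"]
  flux <- exchangeSeries(res)$heterolactic[, rid]
  recon <- sum(flux[-1] * bio[-length(bio)] * res@configEcho$dt)
  expect_equal(lac$net[nrow(lac)], recon, tolerance = 1e-9 * max(1, recon))
})
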