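test_that("biomass bins use the printed 250/500/750 edges, half-open", {
  expect_equal(as.character(binBiomass(c(0, 100, 249.9, 250, 300, 499.9,
                                         500, 700, 750))),
               c("weak", "weak", "weak", "intermediate", "intermediate",
                 "intermediate", "strong", "strong", "strong"))
})

test_that("the growth grid enumerates singles and cross-genus pairs", {
  sc <- makeCrossfeedingPair()
  suite <- makeMediaSuite()
  cfg <- smallCfg(rows = 8, cols = 8, horizon = 20, seed = 1)
  grid <- suppressWarnings(growthGrid(
    list(sc$producer, sc$consumer), suite["limiting"], config = cfg,
    nRuns = 2))
  expect_equal(nrow(grid), 3)  # 2 mono + 1 pair
  expect_equal(sum(is.na(grid$species_b)), 2)
  expect_identical(as.character(grid$bin), as.character(binBiomass(grid$total)))
  # all-zero medium: every cell weak
  none <- Medium("none", c(cpd_glc = 0, cpd_S2 = 0, cpd_M = 0))
  grid0 <- suppressWarnings(growthGrid(
    list(sc$producer, sc$consumer), list(none), config = cfg, nRuns = 1))
  expect_true(all(grid0$bin == "weak"))
  # same-genus pairs are excluded by default, included with allPairs
  comp <- makeCompetitorPair()
  g1 <- suppressWarnings(growthGrid(comp, list(none), config = cfg,
                                    nRuns = 1))
  expect_equal(nrow(g1), 2)
  g2 <- suppressWarnings(growthGrid(comp, list(none), config = cfg,
                                    nRuns = 1, allPairs = TRUE))
  expect_equal(nrow(g2), 3)
})

test_that("interaction classification matches its defining cases", {
  expect_identical(unname(classifyInteraction(700, 700, 350, 350)),
                   c("competition", "competition"))
  expect_identical(unname(classifyInteraction(20, 20, 25, 300)),
                   c("neutral", "stimulation"))
  expect_identical(unname(classifyInteraction(500, 500, 500, 500)),
                   c("neutral", "neutral"))
  expect_identical(unname(classifyInteraction(600, 300, 200, 320)),
                   c("inhibition", "neutral"))
  expect_identical(unname(classifyInteraction(0, 10, 0, 10)),
                   c("neutral", "neutral"))
  # label-swap symmetry on random inputs
  set.seed(7)
  for (k in 1:50) {
    x <- stats::runif(4, 0, 800)
    ab <- classifyInteraction(x[1], x[2], x[3], x[4])
    ba <- classifyInteraction(x[2], x[1], x[4], x[3])
    expect_identical(unname(ab), unname(rev(ba)))
  }
})

test_that("designed interactions classify identically across 12 seeds", {
  sc <- makeCrossfeedingPair()
  comp <- makeCompetitorPair()
  suite <- makeMediaSuite()
  cfg0 <- smallCfg(rows = 8, cols = 8, horizon = 30)
  for (seed in 1:12) {
    cfg <- cfg0; cfg@seed <- as.integer(seed)
    # competitors on rich: both halve -> competition/competition
    mono1 <- finalBiomass(quietSim(comp[[1]], suite$rich,
                                   c(competitor_1 = 3), cfg), "competitor_1")
    mono2 <- finalBiomass(quietSim(comp[[2]], suite$rich,
                                   c(competitor_2 = 3), cfg), "competitor_2")
    both <- quietSim(comp, suite$rich,
                     c(competitor_1 = 3, competitor_2 = 3), cfg)
    cls <- classifyInteraction(mono1, mono2,
                               finalBiomass(both, "competitor_1"),
                               finalBiomass(both, "competitor_2"))
    expect_identical(unname(cls), c("competition", "competition"))
    # producer + auxotrophic consumer on the limiting medium
    monoP <- finalBiomass(quietSim(sc$producer, suite$limiting,
                                   c(producer = 3), cfg), "producer")
    monoC <- finalBiomass(quietSim(sc$consumer, suite$limiting,
                                   c(consumer = 3), cfg), "consumer")
    co <- quietSim(list(sc$producer, sc$consumer), suite$limiting,
                   c(producer = 3, consumer = 3), cfg)
    cls2 <- classifyInteraction(monoP, monoC,
                                finalBiomass(co, "producer"),
                                finalBiomass(co, "consumer"))
    expect_identical(unname(cls2[2]), "stimulation")
  }
})

test_that("the supplementation screen finds the designed rescue first", {
  sc <- makeCrossfeedingPair()
  suite <- makeMediaSuite()
  cfg <- smallCfg(horizon = 30, seed = 1)
  scr <- suppressWarnings(supplementationScreen(
    sc$consumer, suite$limiting,
    c("cpd_glc", "cpd_M", "cpd_S2", "cpd_mystery"), dose = 10,
    config = cfg))
  expect_identical(scr$metabolite[1], "cpd_M")
  expect_true(scr$promoting[1])
  # a substrate the model cannot even transport changes nothing
  glc <- scr[scr$metabolite == "cpd_glc", ]
  expect_equal(glc$fold_change, 1, tolerance = 1e-6)
  expect_false(glc$promoting)
  # unknown ids are recorded, not fatal
  myst <- scr[scr$metabolite == "cpd_mystery", ]
  expect_false(myst$applicable)
  expect_true(is.na(myst$fold_change))
  # determinism under a fixed seed
  scr2 <- suppressWarnings(supplementationScreen(
    sc$consumer, suite$limiting,
    c("cpd_glc", "cpd_M", "cpd_S2", "cpd_mystery"), dose = 10,
    config = cfg))
  expect_identical(scr, scr2)
  expect_error(suppressWarnings(supplementationScreen(
    sc$consumer, suite$limiting, "cpd_M", dose = 0, config = cfg)))
})

test_that("dose responses are reported per dose and reproducible", {
  sc <- makeCrossfeedingPair()
  suite <- makeMediaSuite()
  cfg <- smallCfg(horizon = 25, seed = 3)
  base <- suppressWarnings(
    doseResponse(sc$consumer, suite$limiting, "cpd_M", doses = 0,
                 config = cfg))
  expect_equal(nrow(base), 1)
  expect_equal(base$final_biomass,
               finalBiomass(quietSim(sc$consumer, suite$limiting,
                                     c(consumer = 5), cfg), "consumer"))
  dr <- suppressWarnings(
    doseResponse(sc$consumer, suite$limiting, "cpd_M",
                 doses = c(0, doseLadder()), config = cfg))
  # rescue metabolite: nondecreasing until another resource limits
  expect_true(all(diff(dr$final_biomass) >= -1e-9))
  dup <- suppressWarnings(
    doseResponse(sc$consumer, suite$limiting, "cpd_M", doses = c(1, 1),
                 config = cfg))
  expect_equal(dup$final_biomass[1], dup$final_biomass[2])
})
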