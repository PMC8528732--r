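test_that("chain-model FBA matches the closed form and the simplex oracle", {
  for (vmax in c(2, 5, 10)) for (yield in c(0.05, 0.1, 0.5)) {
    m <- makeChainSpecies("toy", yield = yield, vmax = vmax)
    sol <- solveFBA(m)
    expect_equal(solutionStatus(sol), "optimal")
    expect_equal(growthRate(sol), vmax * yield, tolerance = 1e-10)
    # steady state and bounds hold
    v <- fluxes(sol)
    expect_lt(max(abs(as.matrix(stoichiometry(m)) %*% v)), 1e-8)
    rxn <- reactions(m)
    expect_true(all(v >= rxn$lb - 1e-9 & v <= rxn$ub + 1e-9))
    # independent oracle agrees
    orc <- oracleFBA(m)
    expect_equal(orc$solved, 1)
    expect_equal(growthRate(sol), orc$value, tolerance = 1e-8)
  }
})

test_that("closed exchanges stop growth; bad overrides are errors", {
  m <- makeChainSpecies("toy")
  closed <- list(EX_cpd_glc = c(0, 1000))
  expect_equal(growthRate(solveFBA(m, closed)), 0)
  expect_error(solveFBA(m, list(EX_cpd_glc = c(5, -5))), "lb > ub")
  expect_error(solveFBA(m, list(nope = c(0, 1))), "unknown reaction")
})

test_that("optimum is invariant to reaction order and repeated solves", {
  pair <- makeCrossfeedingPair()
  m <- pair$consumer
  ov <- mediumBounds(m, makeMediaSuite()$rich)
  ref <- solveFBA(m, ov)
  expect_identical(fluxes(solveFBA(m, ov)), fluxes(ref))  # restart-stable
  set.seed(42)
  for (k in 1:5) {
    perm <- sample(nrow(reactions(m)))
    rxn <- reactions(m)[perm, ]
    S <- stoichiometry(m)[, perm]
    m2 <- MetabolicModel(speciesId(m), metabolites(m), rxn,
                         as.matrix(S), biomassId(m))
    rel <- abs(growthRate(solveFBA(m2, ov)) - growthRate(ref)) /
      max(1, abs(growthRate(ref)))
    expect_lt(rel, 1e-6)
  }
})

test_that("relaxing exchange lower bounds never decreases the optimum", {
  models <- list(makeChainSpecies("a"), makeHeterolacticSpecies(),
                 makeCrossfeedingPair()$producer)
  for (m in models) {
    rxn <- reactions(m)
    mu1 <- growthRate(solveFBA(m))
    wide <- setNames(lapply(which(rxn$exchange), function(j)
      c(2 * rxn$lb[j], rxn$ub[j])), rxn$id[rxn$exchange])
    mu2 <- growthRate(solveFBA(m, wide))
    expect_gte(mu2, mu1 - 1e-9)
  }
})

test_that("infeasible steady states return zero growth and empty fluxes", {
  m <- adhocModel("stuck",
    rbind(met("cpd_y", "external"), met("cpd_y_c"), met("cpd_x_c")),
    rbind(rxnrow("EX_cpd_y", -10, 1000, exchange = TRUE),
          rxnrow("T_y", 0, 1000),
          rxnrow("SRC", 1, 2),            # forces production of cpd_x_c
          rxnrow("BIOMASS", 0, 1000, objective = 1)),
    list(EX_cpd_y = c(cpd_y = -1),
         T_y = c(cpd_y = -1, cpd_y_c = 1),
         SRC = c(cpd_x_c = 1),            # dead end: nothing consumes it
         BIOMASS = c(cpd_y_c = -10)))
  sol <- solveFBA(m)
  expect_equal(solutionStatus(sol), "infeasible")
  expect_equal(growthRate(sol), 0)
  expect_length(fluxes(sol), 0)
})

test_that("blocked reactions: dead ends are found and brute force agrees", {
  chain <- makeChainSpecies("toy")
  expect_length(findBlockedReactions(chain)$blocked, 0)

  dead <- adhocModel("dead",
    rbind(met("cpd_glc", "external"), met("cpd_glc_c"), met("cpd_d_c")),
    rbind(rxnrow("EX_cpd_glc", -10, 1000, exchange = TRUE),
          rxnrow("T_glc", 0, 1000),
          rxnrow("R_DEAD", 0, 1000),
          rxnrow("BIOMASS", 0, 1000, objective = 1)),
    list(EX_cpd_glc = c(cpd_glc = -1),
         T_glc = c(cpd_glc = -1, cpd_glc_c = 1),
         R_DEAD = c(cpd_glc_c = -1, cpd_d_c = 1),  # cpd_d_c has no sink
         BIOMASS = c(cpd_glc_c = -10)))
  res <- findBlockedReactions(dead)
  expect_identical(res$blocked, "R_DEAD")
  expect_equal(res$percentage, 25)  # 1 of 4 reactions

  for (m in list(chain, dead, makeCrossfeedingPair()$consumer,
                 makeHeterolacticSpecies()))
    expect_setequal(findBlockedReactions(m)$blocked, oracleBlocked(m))
})

test_that("mass/charge balance bookkeeping finds designed imbalances", {
  m <- adhocModel("chem",
    rbind(met("cpd_glc", "external", "C6H12O6", 0),
          met("cpd_glc_c", formula = "C6H12O6", charge = 0),
          met("cpd_lac_c", formula = "C3H6O3", charge = -1),
          met("cpd_f_c", formula = "CH2O", charge = 0),
          met("cpd_g_c", formula = "CH2O", charge = 0),
          met("cpd_co2_c", formula = "CO2", charge = 0),
          met("cpd_u_c"),                       # no formula
          met("cpd_w_c", formula = "not-a-formula")),
    rbind(rxnrow("EX_cpd_glc", -10, 1000, exchange = TRUE),
          rxnrow("T_glc", 0, 1000),
          rxnrow("SPLIT", 0, 1000),
          rxnrow("ISO", -1000, 1000),
          rxnrow("OX", 0, 1000),
          rxnrow("UNK", 0, 1000),
          rxnrow("BAD", 0, 1000),
          rxnrow("BIOMASS", 0, 1000, objective = 1)),
    list(EX_cpd_glc = c(cpd_glc = -1),
         T_glc = c(cpd_glc = -1, cpd_glc_c = 1),
         SPLIT = c(cpd_glc_c = -1, cpd_lac_c = 2),   # C6H12O6 -> 2 C3H6O3
         ISO = c(cpd_f_c = -1, cpd_g_c = 1),         # CH2O -> CH2O
         OX = c(cpd_f_c = -1, cpd_co2_c = 1),        # CH2O -> CO2
         UNK = c(cpd_u_c = -1, cpd_g_c = 1),
         BAD = c(cpd_w_c = -1, cpd_g_c = 1),
         BIOMASS = c(cpd_lac_c = -10)))
  rep <- checkBalances(m)
  stat <- setNames(rep$status, rep$reaction)
  expect_false("EX_cpd_glc" %in% rep$reaction)   # exchanges excluded
  expect_false("BIOMASS" %in% rep$reaction)      # pseudo-reaction excluded
  expect_equal(stat[["T_glc"]], "balanced")
  expect_equal(stat[["ISO"]], "balanced")
  expect_equal(stat[["OX"]], "imbalanced")
  expect_match(rep$detail[rep$reaction == "OX"], "H -2")
  expect_match(rep$detail[rep$reaction == "OX"], "O \\+1")
  expect_equal(stat[["UNK"]], "unchecked")
  expect_equal(stat[["BAD"]], "unchecked")
  # charge imbalance: SPLIT is mass-balanced but 0 -> 2x(-1) charges
  expect_equal(stat[["SPLIT"]], "imbalanced")
  expect_match(rep$detail[rep$reaction == "SPLIT"], "charge -2")
})

test_that("parsimonious flag removes futile-cycle flux at equal optimum", {
  base <- makeChainSpecies("loopy")
  mets <- rbind(metabolites(base), met("cpd_a_c"), met("cpd_b_c"))
  rxn <- rbind(reactions(base),
               rxnrow("CYC1", -1000, 1000), rxnrow("CYC2", -1000, 1000))
  S <- as.matrix(stoichiometry(base))
  S <- cbind(rbind(S, matrix(0, 2, ncol(S))),
             CYC1 = c(0, 0, -1, 1), CYC2 = c(0, 0, 1, -1))
  rownames(S) <- mets$id
  m <- MetabolicModel("loopy", mets, rxn, S, "BIOMASS")
  plain <- solveFBA(m)
  pfba <- solveFBA(m, pfba = TRUE)
  expect_equal(growthRate(pfba), growthRate(plain), tolerance = 1e-9)
  expect_lte(sum(abs(fluxes(pfba))), sum(abs(fluxes(plain))) + 1e-9)
  expect_lt(max(abs(fluxes(pfba)[c("CYC1", "CYC2")])), 1e-8)
})

test_that("toy_json round-trips and SBML import is consistent with it", {
  dir <- withr::local_tempdir()
  for (m in list(makeChainSpecies("toy"), makeHeterolacticSpecies(),
                 makeCrossfeedingPair()$producer)) {
    jp <- file.path(dir, paste0(speciesId(m), ".json"))
    writeModel(m, jp)
    back <- readModel(jp)
    expect_equal(back, m)

    sp <- file.path(dir, paste0(speciesId(m), ".xml"))
    writeModel(m, sp, format = "sbml")
    sb <- readModel(sp)   # extension-based dispatch
    expect_identical(speciesId(sb), speciesId(m))
    expect_identical(biomassId(sb), biomassId(m))
    expect_equal(as.matrix(stoichiometry(sb))[metabolites(m)$id,
                                              reactions(m)$id],
                 as.matrix(stoichiometry(m)))
    expect_equal(reactions(sb)$lb, reactions(m)$lb)
    expect_equal(reactions(sb)$ub, reactions(m)$ub)
    expect_identical(reactions(sb)$exchange, reactions(m)$exchange)
    expect_equal(growthRate(solveFBA(sb)), growthRate(solveFBA(m)),
                 tolerance = 1e-10)
  }
})

test_that("SBML without an objective is an explicit error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.xml")
  writeModel(makeChainSpecies("toy"), p, format = "sbml")
  ln <- readLines(p)
  drop <- grep("fbc:(listOfObjectives|objective|listOfFluxObjectives|fluxObjective)",
               ln)
  writeLines(ln[-drop], p)
  expect_error(readModel(p), "objective")
})

test_that("model validity rejects broken structures", {
  good <- makeChainSpecies("toy")
  expect_error(MetabolicModel("x", metabolites(good), reactions(good),
                              as.matrix(stoichiometry(good)), "NOPE"),
               "biomass")
  rxn <- reactions(good); rxn$lb[1] <- 9999  # lb > ub
  expect_error(MetabolicModel("x", metabolites(good), rxn,
                              as.matrix(stoichiometry(good)), "BIOMASS"),
               "lb <= ub")
  expect_error(MetabolicModel("x", metabolites(good), reactions(good),
                              list(EX_cpd_glc = c(ghost = -1),
                                   T_cpd_glc = c(cpd_glc = -1, cpd_glc_c = 1),
                                   BIOMASS = c(cpd_glc_c = -10)),
                              "BIOMASS"),
               "ghost")
})
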