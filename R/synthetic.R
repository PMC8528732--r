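## Generators of small synthetic metabolic models and media with designed,
## analytically known behaviour.  They make every pipeline stage testable
## with exact ground truth: a linear-chain grower whose FBA optimum is
## vmax * yield in closed form, an obligate producer -> auxotrophic
## consumer cross-feeding pair, an identical-competitor pair, and a
## heterolactic (lactate + acetate secreting) fermenter.
##
## Secretion in these models is stoichiometrically coupled to the biomass
## reaction (obligate overflow) rather than left optional, so alternate
## FBA optima can never hide the designed secretion.  Toy ids use a
## neutral namespace (cpd_glc, cpd_M, cpd_o2, ...); internal counterparts
## carry the "_c" suffix.

#' Designed ground truth of a synthetic scenario
#'
#' @slot scenario scenario id.
#' @slot designedExchanges \code{data.frame}: \code{producer},
#'   \code{consumer}, \code{metabolite}.
#' @slot analyticGrowth \code{data.frame}: \code{species}, \code{medium},
#'   \code{mu} (closed-form growth rate, h\eqn{^{-1}}), verified against
#'   [solveFBA()] at build time.
#' @slot expectedClassification \code{data.frame}: \code{species_a},
#'   \code{species_b}, \code{class_a}, \code{class_b}.
#' @export
setClass("GroundTruth",
  representation(scenario = "character", designedExchanges = "data.frame",
                 analyticGrowth = "data.frame",
                 expectedClassification = "data.frame"))

#' Uptake bounds realising a medium in plain (non-dynamic) FBA
#'
#' Closes the uptake of every exchange whose metabolite is absent from
#' the medium (or present at zero concentration); uptake of present
#' metabolites keeps the model's own bound.  Used to verify closed-form
#' growth rates outside the arena.
#'
#' @param model a [MetabolicModel-class].
#' @param medium a [Medium-class].
#' @return named list of \code{c(lb, ub)} overrides for [solveFBA()].
#' @export
mediumBounds <- function(model, medium) {
  ex <- exchangeReactions(model)
  rxn <- model@reactions
  comp <- medium@components
  out <- list()
  for (k in seq_len(nrow(ex))) {
    present <- ex$metabolite[k] %in% names(comp) &&
      comp[[ex$metabolite[k]]] > 0
    if (!present) {
      j <- match(ex$reaction[k], rxn$id)
      out[[ex$reaction[k]]] <- c(max(rxn$lb[j], 0), rxn$ub[j])
    }
  }
  out
}

.toyMet <- function(id, compartment) {
  data.frame(id = id, name = id, compartment = compartment,
             formula = NA_character_, charge = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Minimal linear-chain species
#'
#' Exchange -> transport -> biomass on a single substrate.  The biomass
#' reaction consumes 1/yield mmol of internal substrate per gDW, and the
#' exchange lower bound is -vmax, so the FBA optimum is exactly
#' \eqn{\mu = vmax \times yield} on any medium containing the substrate.
#'
#' @param speciesId species id.
#' @param substrate external metabolite id (also the medium key).
#' @param yield biomass yield in gDW per mmol substrate.
#' @param vmax maximal uptake rate, mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}}.
#' @return a [MetabolicModel-class].
#' @examples
#' growthRate(solveFBA(makeChainSpecies("toy")))  # 0.1 * 10 = 1
#' @export
makeChainSpecies <- function(speciesId = "chain", substrate = "cpd_glc",
                             yield = 0.1, vmax = 10) {
  stopifnot(yield > 0, vmax > 0)
  subc <- paste0(substrate, "_c")
  met <- rbind(.toyMet(substrate, "external"), .toyMet(subc, "internal"))
  rxn <- data.frame(
    id = c(paste0("EX_", substrate), paste0("T_", substrate), "BIOMASS"),
    lb = c(-vmax, 0, 0), ub = c(1000, 1000, 1000),
    exchange = c(TRUE, FALSE, FALSE), objective = c(0, 0, 1),
    stringsAsFactors = FALSE)
  stoich <- setNames(list(
    setNames(-1, substrate),
    setNames(c(-1, 1), c(substrate, subc)),
    setNames(-1 / yield, subc)), rxn$id)
  MetabolicModel(speciesId, met, rxn, stoich, "BIOMASS")
}

#' Obligate producer / auxotrophic consumer cross-feeding pair
#'
#' The producer grows on \code{cpd_glc} and co-secretes the cross-fed
#' metabolite stoichiometrically with biomass (\code{secretion} mmol per
#' gDW formed), so secretion is guaranteed at any optimum.  The consumer
#' grows on its own substrate \code{cpd_S2} but its biomass additionally
#' requires \code{requirement} mmol of the metabolite per gDW, which it
#' cannot synthesise: on a medium lacking the metabolite its growth rate
#' is exactly 0, and co-culture with the producer (or supplementation)
#' rescues it.
#'
#' @param metabolite the cross-fed metabolite id.
#' @param yield,vmax chain parameters shared by both species.
#' @param secretion mmol of metabolite secreted per gDW of producer
#'   biomass.
#' @param requirement mmol of metabolite required per gDW of consumer
#'   biomass.
#' @return list with \code{producer}, \code{consumer} (both
#'   [MetabolicModel-class]) and \code{groundTruth}
#'   ([GroundTruth-class], verified against [solveFBA()] on the
#'   [makeMediaSuite()] media at build time).
#' @export
makeCrossfeedingPair <- function(metabolite = "cpd_M", yield = 0.1,
                                 vmax = 10, secretion = 5,
                                 requirement = 1) {
  metc <- paste0(metabolite, "_c")

  ## producer: glucose chain + obligate co-secretion of the metabolite
  met <- rbind(.toyMet("cpd_glc", "external"), .toyMet("cpd_glc_c", "internal"),
               .toyMet(metabolite, "external"), .toyMet(metc, "internal"))
  rxn <- data.frame(
    id = c("EX_cpd_glc", "T_cpd_glc", paste0("T_", metabolite),
           paste0("EX_", metabolite), "BIOMASS"),
    lb = c(-vmax, 0, 0, 0, 0), ub = rep(1000, 5),
    exchange = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    objective = c(0, 0, 0, 0, 1), stringsAsFactors = FALSE)
  stoich <- setNames(list(
    setNames(-1, "cpd_glc"),
    setNames(c(-1, 1), c("cpd_glc", "cpd_glc_c")),
    setNames(c(-1, 1), c(metc, metabolite)),
    setNames(-1, metabolite),
    setNames(c(-1 / yield, secretion), c("cpd_glc_c", metc))), rxn$id)
  producer <- MetabolicModel("producer", met, rxn, stoich, "BIOMASS")

  ## consumer: own substrate + auxotrophy for the metabolite
  met <- rbind(.toyMet("cpd_S2", "external"), .toyMet("cpd_S2_c", "internal"),
               .toyMet(metabolite, "external"), .toyMet(metc, "internal"))
  rxn <- data.frame(
    id = c("EX_cpd_S2", "T_cpd_S2", paste0("EX_", metabolite),
           paste0("T_", metabolite), "BIOMASS"),
    lb = c(-vmax, 0, -vmax, 0, 0), ub = rep(1000, 5),
    exchange = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    objective = c(0, 0, 0, 0, 1), stringsAsFactors = FALSE)
  stoich <- setNames(list(
    setNames(-1, "cpd_S2"),
    setNames(c(-1, 1), c("cpd_S2", "cpd_S2_c")),
    setNames(-1, metabolite),
    setNames(c(-1, 1), c(metabolite, metc)),
    setNames(c(-1 / yield, -requirement), c("cpd_S2_c", metc))), rxn$id)
  consumer <- MetabolicModel("consumer", met, rxn, stoich, "BIOMASS")

  mu <- yield * vmax
  muM <- min(mu, vmax / requirement)  # consumer with the metabolite present
  suite <- makeMediaSuite(metabolite)
  gt <- new("GroundTruth", scenario = "crossfeed",
    designedExchanges = data.frame(producer = "producer",
                                   consumer = "consumer",
                                   metabolite = metabolite,
                                   stringsAsFactors = FALSE),
    analyticGrowth = data.frame(
      species = c("producer", "producer", "producer",
                  "consumer", "consumer", "consumer"),
      medium = rep(c("rich", "limiting", "limitingM"), 2),
      mu = c(mu, mu, mu, muM, 0, muM), stringsAsFactors = FALSE),
    expectedClassification = data.frame(
      species_a = "producer", species_b = "consumer",
      class_a = "neutral", class_b = "stimulation",
      stringsAsFactors = FALSE))
  .verifyGroundTruth(gt, list(producer = producer, consumer = consumer),
                     suite)
  list(producer = producer, consumer = consumer, groundTruth = gt)
}

.verifyGroundTruth <- function(gt, models, media, tol = 1e-8) {
  ag <- gt@analyticGrowth
  for (i in seq_len(nrow(ag))) {
    model <- models[[ag$species[i]]]
    medium <- media[[ag$medium[i]]]
    mu <- growthRate(solveFBA(model, mediumBounds(model, medium)))
    if (abs(mu - ag$mu[i]) > tol)
      stop(sprintf(
        "ground-truth mismatch: %s on %s gives mu=%.10g, expected %.10g",
        ag$species[i], ag$medium[i], mu, ag$mu[i]))
  }
  invisible(TRUE)
}

#' Identical-competitor pair
#'
#' Two label-distinct copies of one model (identical stoichiometry), for
#' pure space/resource competition: in co-culture on a rich medium each
#' copy is expected to reach about half of the arena biomass capacity,
#' while either alone saturates it.
#'
#' @param base template model; default a glucose chain species.
#' @return list of two [MetabolicModel-class] objects with ids
#'   \code{<base>_1} and \code{<base>_2}.
#' @export
makeCompetitorPair <- function(base = makeChainSpecies("competitor")) {
  a <- base; b <- base
  a@speciesId <- paste0(speciesId(base), "_1")
  b@speciesId <- paste0(speciesId(base), "_2")
  list(a, b)
}

#' Heterolactic fermenter
#'
#' A glucose consumer that secretes both lactate and acetate, with the
#' flux split fixed by the biomass stoichiometry (obligate co-secretion),
#' so the acetate:lactate secretion ratio equals
#' \code{acetate / lactate} exactly at any optimum.
#'
#' @param speciesId species id.
#' @param yield,vmax chain parameters.
#' @param lactate,acetate mmol secreted per gDW of biomass formed.
#' @return a [MetabolicModel-class].
#' @export
makeHeterolacticSpecies <- function(speciesId = "heterolactic", yield = 0.1,
                                    vmax = 10, lactate = 4, acetate = 2) {
  met <- rbind(.toyMet("cpd_glc", "external"), .toyMet("cpd_glc_c", "internal"),
               .toyMet("cpd_lac", "external"), .toyMet("cpd_lac_c", "internal"),
               .toyMet("cpd_ac", "external"), .toyMet("cpd_ac_c", "internal"))
  rxn <- data.frame(
    id = c("EX_cpd_glc", "T_cpd_glc", "T_cpd_lac", "EX_cpd_lac",
           "T_cpd_ac", "EX_cpd_ac", "BIOMASS"),
    lb = c(-vmax, 0, 0, 0, 0, 0, 0), ub = rep(1000, 7),
    exchange = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    objective = c(0, 0, 0, 0, 0, 0, 1), stringsAsFactors = FALSE)
  stoich <- setNames(list(
    setNames(-1, "cpd_glc"),
    setNames(c(-1, 1), c("cpd_glc", "cpd_glc_c")),
    setNames(c(-1, 1), c("cpd_lac_c", "cpd_lac")),
    setNames(-1, "cpd_lac"),
    setNames(c(-1, 1), c("cpd_ac_c", "cpd_ac")),
    setNames(-1, "cpd_ac"),
    setNames(c(-1 / yield, lactate, acetate),
             c("cpd_glc_c", "cpd_lac_c", "cpd_ac_c"))), rxn$id)
  MetabolicModel(speciesId, met, rxn, stoich, "BIOMASS")
}

#' Synthetic media suite
#'
#' Three media mirroring the permissive / selective-limiting /
#' supplemented-rescue design: \code{rich} supports all toy species
#' (glucose and the consumer substrate at 20 mM, the cross-fed metabolite
#' at 10 mM), \code{limiting} zeroes the cross-fed metabolite and supplies
#' only a small glucose pool (2 uM, enough for a few hundred pg of
#' producer biomass) so that neither capacity nor space is exhausted by
#' the producer, and \code{limitingM} is \code{limiting} supplemented with
#' 10 mM of the metabolite.  All three hold oxygen at 0.1 mM, replenished
#' every step (microaerobic environment).
#'
#' @param metabolite the cross-fed metabolite id.
#' @return named list of three [Medium-class] objects:
#'   \code{rich}, \code{limiting}, \code{limitingM}.
#' @export
makeMediaSuite <- function(metabolite = "cpd_M") {
  rich <- Medium("rich",
    setNames(c(20, 20, 10, 0.1),
             c("cpd_glc", "cpd_S2", metabolite, "cpd_o2")),
    replenished = "cpd_o2")
  limiting <- Medium("limiting",
    setNames(c(0.002, 20, 0, 0.1),
             c("cpd_glc", "cpd_S2", metabolite, "cpd_o2")),
    replenished = "cpd_o2")
  limitingM <- supplementMedium(limiting, metabolite, 10)
  limitingM@name <- "limitingM"
  list(rich = rich, limiting = limiting, limitingM = limitingM)
}

#' Write the synthetic fixture set to a directory
#'
#' Emits the toy models as toy_json and the media suite as TSV, so that
#' the command-line pipeline (and external tools) can run on a
#' self-contained scenario directory.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeFixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- makeCrossfeedingPair()
  comp <- makeCompetitorPair()
  het <- makeHeterolacticSpecies()
  suite <- makeMediaSuite()
  paths <- c(
    writeModel(pair$producer, file.path(dir, "producer.json")),
    writeModel(pair$consumer, file.path(dir, "consumer.json")),
    writeModel(comp[[1]], file.path(dir, "competitor_1.json")),
    writeModel(comp[[2]], file.path(dir, "competitor_2.json")),
    writeModel(het, file.path(dir, "heterolactic.json")),
    writeMedium(suite$rich, file.path(dir, "rich.tsv")),
    writeMedium(suite$limiting, file.path(dir, "limiting.tsv")),
    writeMedium(suite$limitingM, file.path(dir, "limitingM.tsv")))
  invisible(paths)
}
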