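## In-silico experiment designs: the mono/pair growth grid with biomass
## binning, interaction classification, and the single-metabolite
## supplementation ("prebiotic") screen with dose-response profiling.

#' Bin a total final biomass into the growth categories
#'
#' Fixed edges on total produced biomass at the horizon: weak [0, 250) pg,
#' intermediate [250, 500) pg, strong [500, 750] pg.
#'
#' @param total final biomass in pg (vectorised).
#' @return factor with levels weak/intermediate/strong.
#' @export
binBiomass <- function(total) {
  cut(total, breaks = c(0, 250, 500, Inf), right = FALSE,
      labels = c("weak", "intermediate", "strong"), include.lowest = TRUE)
}

.genusOf <- function(speciesId) sub("[_ ].*$", "", speciesId)

#' Mono- and pair-wise growth grid
#'
#' Simulates every single species and every unordered species pair on
#' every medium (cross-genus pairs only by default, where the genus is the
#' species-id prefix before the first underscore), each via
#' [runReplicates()], and records the mean final biomasses with the growth
#' bin of the total.
#'
#' @param models list of [MetabolicModel-class] objects.
#' @param media list of [Medium-class] objects.
#' @param inoculumSize agents per species at t = 0.
#' @param config an [ArenaConfig-class]; the horizon defaults to 45 h.
#' @param nRuns replicates per grid cell.
#' @param allPairs include same-genus pairs too?
#' @return \code{data.frame}: \code{species_a}, \code{species_b} (\code{NA}
#'   for mono-cultures), \code{medium}, \code{final_a}, \code{final_b},
#'   \code{total}, \code{bin}.
#' @export
growthGrid <- function(models, media, inoculumSize = 5L,
                       config = arenaConfig(), nRuns = 12,
                       allPairs = FALSE) {
  if (is(models, "MetabolicModel")) models <- list(models)
  if (is(media, "Medium")) media <- list(media)
  stopifnot(length(models) >= 1L, length(media) >= 1L)
  ids <- vapply(models, speciesId, character(1))
  names(models) <- ids
  combos <- lapply(ids, function(a) c(a, NA_character_))
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      if (!allPairs && .genusOf(ids[i]) == .genusOf(ids[j])) next
      combos <- c(combos, list(c(ids[i], ids[j])))
    }
  }
  rows <- list()
  for (medium in media) for (cmb in combos) {
    inoc <- setNames(rep(inoculumSize, sum(!is.na(cmb))),
                     cmb[!is.na(cmb)])
    use <- models[cmb[!is.na(cmb)]]
    res <- runReplicates(use, medium, inoc, config, nRuns = nRuns)$mean
    fin <- res@biomass[nrow(res@biomass), ]
    fa <- unname(fin[cmb[1]])
    fb <- if (is.na(cmb[2])) NA_real_ else unname(fin[cmb[2]])
    rows[[length(rows) + 1L]] <- data.frame(
      species_a = cmb[1], species_b = cmb[2], medium = medium@name,
      final_a = fa, final_b = fb, total = sum(fin),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$bin <- binBiomass(out$total)
  out
}

#' Classify a pairwise growth interaction
#'
#' Compares each species' final biomass in co-culture with its
#' mono-culture value.  Per species: \emph{stimulation} when the
#' co-culture biomass reaches at least \code{sigma} times the mono-culture
#' value (and exceeds it); \emph{competition} when both species are
#' decreased; \emph{inhibition} when the species drops to at most
#' \code{iota} times its mono value while the partner is not decreased;
#' otherwise \emph{neutral}.  Swapping the two species swaps the labels
#' consistently.
#'
#' @param monoA,monoB mono-culture final biomasses (pg).
#' @param pairA,pairB co-culture final biomasses (pg).
#' @param sigma stimulation fold threshold (default 2).
#' @param iota inhibition fold threshold (default 0.5).
#' @return named character vector \code{c(a = ..., b = ...)} with levels
#'   competition/inhibition/stimulation/neutral.
#' @examples
#' classifyInteraction(700, 700, 360, 360)  # competition / competition
#' classifyInteraction(20, 20, 25, 300)     # neutral / stimulation
#' @export
classifyInteraction <- function(monoA, monoB, pairA, pairB,
                                sigma = 2, iota = 0.5) {
  stopifnot(monoA >= 0, monoB >= 0, pairA >= 0, pairB >= 0)
  one <- function(mono, pair, monoP, pairP) {
    if (mono == 0 && pair == 0) return("neutral")
    if (pair > mono && pair >= sigma * mono) return("stimulation")
    if (pair < mono && pairP < monoP) return("competition")
    if (pair <= iota * mono && pairP >= monoP) return("inhibition")
    "neutral"
  }
  c(a = one(monoA, pairA, monoB, pairB),
    b = one(monoB, pairB, monoA, pairA))
}

#' Single-metabolite supplementation screen
#'
#' For each candidate metabolite, simulates the mono-culture on the base
#' medium supplemented with one dose of the candidate and compares the
#' final biomass with the unsupplemented baseline.  A candidate is called
#' \emph{promoting} when the fold change reaches \code{foldThreshold} and
#' the absolute gain reaches \code{gainThreshold} (both configurable and
#' echoed in the output attributes).  Candidates unknown to both the
#' medium and the model namespace are recorded as not applicable, not an
#' error.
#'
#' @param model a [MetabolicModel-class].
#' @param baseMedium a [Medium-class] (e.g. the defined diet).
#' @param candidates character vector of metabolite ids.
#' @param dose supplementation dose in mM (> 0); default 10.
#' @param inoculumSize agents at t = 0.
#' @param config an [ArenaConfig-class].
#' @param nRuns replicates per condition.
#' @param foldThreshold,gainThreshold promotion criterion (fold change and
#'   absolute gain in pg).
#' @return \code{data.frame} ranked by fold change: \code{metabolite},
#'   \code{dose_mM}, \code{baseline_final}, \code{supplemented_final},
#'   \code{fold_change}, \code{gain}, \code{promoting}, \code{applicable}.
#' @export
supplementationScreen <- function(model, baseMedium, candidates, dose = 10,
                                  inoculumSize = 5L, config = arenaConfig(),
                                  nRuns = 1, foldThreshold = 2,
                                  gainThreshold = 10) {
  stopifnot(dose > 0, length(candidates) >= 1L)
  inoc <- setNames(inoculumSize, speciesId(model))
  base <- runReplicates(list(model), baseMedium, inoc, config,
                        nRuns = nRuns)$mean
  b0 <- base@biomass[nrow(base@biomass), speciesId(model)]
  known <- union(names(baseMedium@components), model@metabolites$id)
  rows <- lapply(candidates, function(met) {
    if (!(met %in% known))
      return(data.frame(metabolite = met, dose_mM = dose,
                        baseline_final = b0, supplemented_final = NA_real_,
                        fold_change = NA_real_, gain = NA_real_,
                        promoting = NA, applicable = FALSE,
                        stringsAsFactors = FALSE))
    med <- supplementMedium(baseMedium, met, dose)
    res <- runReplicates(list(model), med, inoc, config, nRuns = nRuns)$mean
    bf <- res@biomass[nrow(res@biomass), speciesId(model)]
    fc <- if (b0 > 0) bf / b0 else Inf
    gain <- bf - b0
    data.frame(metabolite = met, dose_mM = dose, baseline_final = b0,
               supplemented_final = bf, fold_change = fc, gain = gain,
               promoting = fc >= foldThreshold && gain >= gainThreshold,
               applicable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$fold_change), -Inf, out$fold_change)), ]
  rownames(out) <- NULL
  attr(out, "foldThreshold") <- foldThreshold
  attr(out, "gainThreshold") <- gainThreshold
  out
}

#' Dose-response of one supplemented metabolite
#'
#' One simulation per dose (monotonicity is reported, never assumed).
#' The conventional ladder is [doseLadder()].
#'
#' @inheritParams supplementationScreen
#' @param metabolite metabolite id to titrate.
#' @param doses numeric vector of doses in mM (>= 0; 0 = baseline).
#' @return \code{data.frame}: \code{dose_mM}, \code{final_biomass}.
#' @export
doseResponse <- function(model, baseMedium, metabolite,
                         doses = doseLadder(), inoculumSize = 5L,
                         config = arenaConfig(), nRuns = 1) {
  stopifnot(all(doses >= 0))
  inoc <- setNames(inoculumSize, speciesId(model))
  fin <- vapply(doses, function(d) {
    med <- if (d > 0) supplementMedium(baseMedium, metabolite, d) else
      baseMedium
    res <- runReplicates(list(model), med, inoc, config, nRuns = nRuns)$mean
    unname(res@biomass[nrow(res@biomass), speciesId(model)])
  }, numeric(1))
  data.frame(dose_mM = doses, final_biomass = fin)
}
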