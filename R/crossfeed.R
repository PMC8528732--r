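## Cross-feeding detection from paired exchange-flux series:
## relative flux ratios per reaction and timepoint, the snapshot ratio
## matrix, and consistency-based exchanged-metabolite calls.

#' Relative flux ratio of one exchange reaction between two species
#'
#' The ratio \eqn{r = v_A / v_B} of the two species' fluxes for the same
#' exchange reaction and timepoint; when \eqn{-1 < r < 1} the reciprocal
#' \eqn{1/r} is reported instead, so that the magnitude always highlights
#' the higher of the two fluxes and \eqn{|value| \ge 1}.  The sign is
#' positive when both fluxes share a direction (both secrete or both take
#' up) and negative when they are opposite -- the signature of a metabolite
#' being passed from one species to the other.  When either flux is zero
#' (within \code{tol}) the metabolite is not shared and \code{NA} is
#' returned.
#'
#' @param vA,vB fluxes in mmol·gDW\eqn{^{-1}}·h\eqn{^{-1}} (numerator /
#'   denominator species); vectorised.
#' @param tol zero-flux tolerance defining "transported".
#' @return numeric ratio(s) with \eqn{|value| \ge 1}, or \code{NA} when not
#'   shared.
#' @examples
#' fluxRatio(2, 1)     # 2
#' fluxRatio(0.5, 1)   # 2  (reciprocal rule)
#' fluxRatio(1, -2)    # -2 (opposite directions)
#' fluxRatio(1, 0)     # NA (not shared)
#' @export
fluxRatio <- function(vA, vB, tol = 1e-8) {
  r <- vA / vB
  r <- ifelse(r > -1 & r < 1, 1 / r, r)
  ifelse(abs(vA) < tol | abs(vB) < tol, NA_real_, r)
}

#' Snapshot matrix of flux ratios between two species
#'
#' One entry per exchange reaction present in either species of a
#' co-culture simulation, evaluated at a single timepoint (default 32 h,
#' the conventional snapshot for the exchange heatmap).  Reactions absent
#' from one of the two models, or carried by only one of them at that
#' time, get \code{NA} ("not shared").
#'
#' @param result a co-culture [SimulationResult-class] containing both
#'   species.
#' @param speciesA,speciesB species ids (numerator / denominator).
#' @param time snapshot time in h; must lie on the recorded grid.
#' @param tol zero-flux tolerance.
#' @return \code{data.frame}: \code{reaction}, \code{metabolite},
#'   \code{vA}, \code{vB}, \code{value}, \code{shared},
#'   \code{numerator_species}, \code{denominator_species}, \code{time}.
#' @export
ratioMatrix <- function(result, speciesA, speciesB, time = 32, tol = 1e-8) {
  stopifnot(is(result, "SimulationResult"))
  for (sp in c(speciesA, speciesB))
    if (!sp %in% names(result@exchange))
      stop("species not in result: ", sp)
  ti <- which(abs(result@times - time) < 1e-9)
  if (length(ti) != 1L)
    stop("time ", time, " h not on the recorded grid (available: ",
         paste(result@times, collapse = ", "), ")")
  exA <- result@exchange[[speciesA]]; exB <- result@exchange[[speciesB]]
  rids <- union(colnames(exA), colnames(exB))
  map <- result@exchangeMap
  vA <- ifelse(rids %in% colnames(exA), exA[ti, ][rids], NA_real_)
  vB <- ifelse(rids %in% colnames(exB), exB[ti, ][rids], NA_real_)
  vA[is.na(vA)] <- 0; vB[is.na(vB)] <- 0
  met <- map$metabolite[match(rids, map$reaction)]
  val <- fluxRatio(vA, vB, tol)
  data.frame(reaction = rids, metabolite = met,
             vA = unname(vA), vB = unname(vB), value = unname(val),
             shared = !is.na(val),
             numerator_species = speciesA, denominator_species = speciesB,
             time = time, stringsAsFactors = FALSE, row.names = NULL)
}

#' Call exchanged metabolites from ratio matrices over time
#'
#' A metabolite is called \emph{exchanged} between two species when its
#' exchange-reaction flux ratio is negative (opposite transport
#' directions) in at least a \code{consistency} fraction of the timepoints
#' where both species carry the reaction, and it is shared in at least
#' \code{minShared} timepoints.  Output is sorted by decreasing mean
#' absolute ratio.
#'
#' @param x either a co-culture [SimulationResult-class] (ratio matrices
#'   are computed at every recorded timepoint) or a list of
#'   [ratioMatrix()] data frames.
#' @param speciesA,speciesB species ids (used when \code{x} is a result).
#' @param consistency required fraction of negative-sign timepoints,
#'   in (0, 1].
#' @param minShared minimum number of shared timepoints.
#' @param tol zero-flux tolerance.
#' @return \code{data.frame}: \code{metabolite}, \code{reaction},
#'   \code{nShared}, \code{negFraction}, \code{meanAbsRatio},
#'   \code{exchanged}; rows with \code{exchanged == TRUE} are the calls.
#' @export
detectExchanged <- function(x, speciesA = NULL, speciesB = NULL,
                            consistency = 0.8, minShared = 3L,
                            tol = 1e-8) {
  stopifnot(consistency > 0, consistency <= 1)
  if (is(x, "SimulationResult")) {
    stopifnot(!is.null(speciesA), !is.null(speciesB))
    mats <- lapply(x@times[-1], function(t)
      ratioMatrix(x, speciesA, speciesB, time = t, tol = tol))
  } else {
    mats <- x
  }
  all <- do.call(rbind, mats)
  byRxn <- split(all, all$reaction)
  out <- do.call(rbind, lapply(byRxn, function(df) {
    sh <- df[df$shared, , drop = FALSE]
    data.frame(metabolite = df$metabolite[1], reaction = df$reaction[1],
               nShared = nrow(sh),
               negFraction = if (nrow(sh)) mean(sh$value < 0) else NA_real_,
               meanAbsRatio = if (nrow(sh)) mean(abs(sh$value)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$exchanged <- !is.na(out$negFraction) & out$nShared >= minShared &
    out$negFraction >= consistency
  out <- out[order(-ifelse(is.na(out$meanAbsRatio), -Inf, out$meanAbsRatio)), ]
  rownames(out) <- NULL
  out
}
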