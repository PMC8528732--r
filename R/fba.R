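## Flux balance analysis on MetabolicModel objects.
## The LP core is the deterministic bounded-variable simplex in src/.

.FLUX_BIG <- 1000  # conventional "unbounded" flux magnitude

#' Solve the flux balance problem of a model
#'
#' Maximises the biomass flux subject to steady state \eqn{S v = 0} and the
#' flux bounds, using a deterministic two-phase simplex (Bland's rule,
#' feasibility/optimality tolerance 1e-9), so repeated calls return the
#' identical flux vector.  Infeasible problems are not an error: for
#' simulation purposes an agent that cannot satisfy steady state neither
#' grows nor exchanges, so the solution carries \code{status = "infeasible"},
#' growth rate 0 and an empty flux vector.
#'
#' With \code{pfba = TRUE} a secondary lexicographic step minimises the
#' total absolute flux at the fixed optimal growth rate
#' (parsimonious FBA), which stabilises flux reports on degenerate optimal
#' faces; it is off by default.
#'
#' @param model a [MetabolicModel-class].
#' @param boundOverrides named list \code{reaction-id -> c(lb, ub)} applied
#'   on top of the model bounds (used by the arena to tighten uptake to the
#'   locally available amount).
#' @param pfba also minimise total absolute flux at the optimum?
#' @param tol solver feasibility/optimality tolerance.
#' @return a [FluxSolution-class].
#' @examples
#' m <- makeChainSpecies("toy", yield = 0.1, vmax = 10)
#' growthRate(solveFBA(m))  # 1.0 = vmax * yield
#' @export
solveFBA <- function(model, boundOverrides = NULL, pfba = FALSE,
                     tol = 1e-9) {
  stopifnot(is(model, "MetabolicModel"))
  rxn <- model@reactions
  lb <- rxn$lb; ub <- rxn$ub
  names(lb) <- names(ub) <- rxn$id
  if (!is.null(boundOverrides) && length(boundOverrides)) {
    bad <- setdiff(names(boundOverrides), rxn$id)
    if (length(bad))
      stop("bound overrides reference unknown reaction(s): ",
           paste(bad, collapse = ", "))
    for (rid in names(boundOverrides)) {
      bo <- boundOverrides[[rid]]
      if (bo[1] > bo[2])
        stop(sprintf("bound override for reaction '%s' has lb > ub", rid))
      lb[rid] <- bo[1]; ub[rid] <- bo[2]
    }
  }
  A <- as.matrix(model@stoichiometry)
  cobj <- rxn$objective
  sol <- lpSolveDense(A, rep(0, nrow(A)), cobj, unname(lb), unname(ub),
                      tol = tol)
  if (sol$status == 1L)
    return(new("FluxSolution", status = "infeasible", growthRate = 0,
               fluxes = numeric()))
  if (sol$status != 0L)
    stop(sprintf(
      "LP solver failure (status %d) on model '%s' (%d reactions: %s%s)",
      sol$status, model@speciesId, nrow(rxn),
      paste(utils::head(rxn$id, 5), collapse = ", "),
      if (nrow(rxn) > 5) ", ..." else ""))
  v <- setNames(sol$x, rxn$id)
  if (pfba) {
    v2 <- .minimizeAbsFlux(A, lb, ub, cobj, sol$objective, tol)
    if (!is.null(v2)) v <- setNames(v2, rxn$id)
  }
  mu <- max(0, unname(v[model@biomassId]))
  new("FluxSolution", status = "optimal", growthRate = mu, fluxes = v)
}

## min sum |v| at fixed objective value: v = p - q, p,q >= 0
.minimizeAbsFlux <- function(A, lb, ub, cobj, opt, tol) {
  n <- ncol(A)
  A2 <- cbind(A, -A)
  A2 <- rbind(A2, c(cobj, -cobj))        # pin the growth optimum
  b2 <- c(rep(0, nrow(A)), opt)
  lb2 <- rep(0, 2 * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  c2 <- rep(-1, 2 * n)                   # maximise -(sum p + sum q)
  sol <- lpSolveDense(A2, b2, c2, lb2, ub2, tol = tol)
  if (sol$status != 0L) return(NULL)
  sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
}

#' Find blocked reactions
#'
#' A reaction is blocked when it can carry no flux in any feasible steady
#' state once every exchange reaction is fully opened
#' (bounds \eqn{\pm}1000).  Determined by maximising and minimising each
#' reaction's flux (flux variability analysis).
#'
#' @param model a [MetabolicModel-class].
#' @param tol fluxes below this magnitude count as zero.
#' @return list with \code{blocked} (character vector of reaction ids) and
#'   \code{percentage} (share of all reactions, in percent).
#' @export
findBlockedReactions <- function(model, tol = 1e-6) {
  rxn <- model@reactions
  lb <- rxn$lb; ub <- rxn$ub
  lb[rxn$exchange] <- -.FLUX_BIG
  ub[rxn$exchange] <- .FLUX_BIG
  A <- as.matrix(model@stoichiometry)
  b <- rep(0, nrow(A))
  blocked <- character()
  for (j in seq_len(nrow(rxn))) {
    cj <- rep(0, nrow(rxn)); cj[j] <- 1
    hi <- lpSolveDense(A, b, cj, lb, ub)
    lo <- lpSolveDense(A, b, -cj, lb, ub)
    if (hi$status != 0L || lo$status != 0L)
      stop("model infeasible with open exchanges; cannot assess blockage")
    if (abs(hi$objective) < tol && abs(lo$objective) < tol)
      blocked <- c(blocked, rxn$id[j])
  }
  list(blocked = blocked,
       percentage = 100 * length(blocked) / max(1L, nrow(rxn)))
}

#' Check mass and charge balance of internal reactions
#'
#' For every non-exchange reaction with elemental formulas available for
#' all of its metabolites, computes the net elemental (and, when charges
#' are available, charge) imbalance.  Exchange reactions are excluded by
#' definition (they are boundary passages, not chemistry); reactions with
#' missing or unparseable formulas are reported as \code{"unchecked"}.
#'
#' @param model a [MetabolicModel-class].
#' @param checkBiomass biomass pseudo-reactions consume precursors without
#'   products and are never elementally balanced; excluded by default.
#' @return \code{data.frame} with columns \code{reaction}, \code{status}
#'   (\code{balanced} / \code{imbalanced} / \code{unchecked}) and
#'   \code{detail} (per-element net imbalance, e.g. \code{"H -2, O +1"}).
#' @export
checkBalances <- function(model, checkBiomass = FALSE) {
  rxn <- model@reactions
  met <- model@metabolites
  S <- model@stoichiometry
  keep <- !rxn$exchange
  if (!checkBiomass) keep <- keep & rxn$id != model@biomassId
  out <- data.frame(reaction = rxn$id[keep], status = NA_character_,
                    detail = "", stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    j <- match(out$reaction[k], rxn$id)
    nz <- which(S[, j] != 0)
    forms <- met$formula[nz]
    if (anyNA(forms)) { out$status[k] <- "unchecked"; next }
    parsed <- lapply(forms, parseFormula)
    if (any(vapply(parsed, is.null, logical(1)))) {
      out$status[k] <- "unchecked"
      out$detail[k] <- "unparseable formula"
      next
    }
    elems <- unique(unlist(lapply(parsed, names)))
    net <- setNames(numeric(length(elems)), elems)
    for (i in seq_along(nz))
      net[names(parsed[[i]])] <- net[names(parsed[[i]])] +
        S[nz[i], j] * parsed[[i]]
    chg <- met$charge[nz]
    netCharge <- if (anyNA(chg)) NA_real_ else sum(S[nz, j] * chg)
    bad <- net[abs(net) > 1e-9]
    chargeBad <- !is.na(netCharge) && abs(netCharge) > 1e-9
    if (length(bad) == 0L && !chargeBad) {
      out$status[k] <- "balanced"
    } else {
      out$status[k] <- "imbalanced"
      parts <- sprintf("%s %+g", names(bad), unname(bad))
      if (chargeBad) parts <- c(parts, sprintf("charge %+g", netCharge))
      out$detail[k] <- paste(parts, collapse = ", ")
    }
  }
  out
}

#' Parse an elemental formula
#'
#' @param formula e.g. \code{"C6H12O6"}; two-letter element symbols are
#'   supported.
#' @return named numeric vector of element counts, or \code{NULL} when the
#'   string is not a plain elemental formula.
#' @keywords internal
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) return(NULL)
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.numeric(sub("^[A-Za-z]+", "", toks))
  counts[is.na(counts)] <- 1
  out <- tapply(counts, elems, sum)
  setNames(as.numeric(out), names(out))
}
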