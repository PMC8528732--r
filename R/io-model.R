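## Model readers/writers: the package's "toy_json" dialect and SBML L3/FBC.

#' Read a metabolic model
#'
#' Two dialects are supported.  \code{"toy_json"} is the package's own
#' JSON schema for small models:
#' \preformatted{
#' {"species_id": "...",
#'  "metabolites": [{"id","name","compartment","formula"?,"charge"?}, ...],
#'  "reactions":   [{"id","stoich":{met:coef,...},"lb","ub",
#'                   "exchange":bool,"objective":0|1}, ...],
#'  "biomass": "reaction-id"}
#' }
#' \code{"sbml"} imports SBML Level 3 files with the \code{fbc} package:
#' species (with \code{fbc:charge} / \code{fbc:chemicalFormula}), reactions
#' with flux-bound parameters, and the active objective.  Reactions moving
#' exactly one metabolite are classified as exchange reactions and their
#' metabolite as external (secretion-positive convention enforced by
#' validity).
#'
#' @param path file path.
#' @param format \code{"toy_json"} or \code{"sbml"} (default guessed from
#'   the file extension).
#' @return a validated [MetabolicModel-class].
#' @seealso [writeModel()]
#' @export
readModel <- function(path, format = c("auto", "toy_json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "toy_json"
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format, toy_json = .readToyJson(path), sbml = .readSBML(path))
}

#' Write a metabolic model
#'
#' \code{toy_json} writing is the exact inverse of reading (object-level
#' round-trip identity); \code{sbml} writes a minimal SBML L3v1 + fbc-v2
#' document sufficient to round-trip through [readModel()].
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @param format \code{"toy_json"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path, format = c("toy_json", "sbml")) {
  format <- match.arg(format)
  if (format == "toy_json") .writeToyJson(model, path) else
    .writeSBML(model, path)
  invisible(path)
}

.readToyJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("species_id", "metabolites", "reactions", "biomass")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("toy_json model is missing field(s): ", paste(miss, collapse = ", "))
  met <- do.call(rbind, lapply(x$metabolites, function(m) data.frame(
    id = m$id, name = if (is.null(m$name)) m$id else m$name,
    compartment = m$compartment,
    formula = if (is.null(m$formula)) NA_character_ else m$formula,
    charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
    stringsAsFactors = FALSE)))
  rxn <- do.call(rbind, lapply(x$reactions, function(r) data.frame(
    id = r$id, lb = r$lb, ub = r$ub, exchange = isTRUE(r$exchange),
    objective = if (is.null(r$objective)) 0 else r$objective,
    stringsAsFactors = FALSE)))
  stoich <- lapply(x$reactions, function(r) unlist(r$stoich))
  names(stoich) <- rxn$id
  if (!x$biomass %in% rxn$id)
    stop("toy_json model: biomass reaction '", x$biomass, "' not defined")
  MetabolicModel(x$species_id, met, rxn, stoich, x$biomass)
}

.writeToyJson <- function(model, path) {
  met <- model@metabolites
  mets <- lapply(seq_len(nrow(met)), function(i) {
    m <- list(id = met$id[i], name = met$name[i],
              compartment = met$compartment[i])
    if (!is.na(met$formula[i])) m$formula <- met$formula[i]
    if (!is.na(met$charge[i])) m$charge <- met$charge[i]
    m
  })
  rxn <- model@reactions
  S <- model@stoichiometry
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    nz <- which(S[, j] != 0)
    list(id = rxn$id[j],
         stoich = as.list(setNames(S[nz, j], met$id[nz])),
         lb = rxn$lb[j], ub = rxn$ub[j], exchange = rxn$exchange[j],
         objective = rxn$objective[j])
  })
  obj <- list(species_id = model@speciesId, metabolites = mets,
              reactions = rxns, biomass = model@biomassId)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

## -- SBML L3 + fbc-v2 ------------------------------------------------------

.sbmlNS <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

.readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- .sbmlNS
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) stop("no <model> element in ", path)

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  spid <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  met <- data.frame(
    id = spid,
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), spid,
                  xml2::xml_attr(sp, "name")),
    compartment = "internal",
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "fbc:charge", ns = ns))),
    stringsAsFactors = FALSE)[!boundary, , drop = FALSE]

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("SBML model has no reactions")
  stoich <- list(); ids <- character(length(rx))
  lbs <- ubs <- numeric(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    ids[i] <- xml2::xml_attr(r, "id")
    lref <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns = ns)
    uref <- xml2::xml_attr(r, "fbc:upperFluxBound", ns = ns)
    rev <- xml2::xml_attr(r, "reversible") %in% "true"
    lbs[i] <- if (!is.na(lref) && lref %in% names(pval)) pval[[lref]] else
      if (rev) -.FLUX_BIG else 0
    ubs[i] <- if (!is.na(uref) && uref %in% names(pval)) pval[[uref]] else
      .FLUX_BIG
    co <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, sprintf("./s:%s/s:speciesReference", side),
                                 ns)
      if (!length(refs)) next
      sids <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      co <- c(co, setNames(st, sids))
    }
    co <- co[names(co) %in% met$id]           # boundary species drop out
    if (length(co)) co <- tapply(co, names(co), sum)
    stoich[[ids[i]]] <- setNames(as.numeric(co), names(co))
  }

  fo <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(fo) == 0L)
    stop("SBML model has no flux objective (fbc:listOfObjectives)")
  objRxn <- xml2::xml_attr(fo, "fbc:reaction", ns = ns)
  objCoef <- as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns = ns))
  objCoef[is.na(objCoef)] <- 1
  biomass <- objRxn[which.max(objCoef)]

  rxn <- data.frame(id = ids, lb = lbs, ub = ubs, exchange = FALSE,
                    objective = 0, stringsAsFactors = FALSE)
  rxn$objective[match(objRxn, rxn$id)] <- objCoef
  ## structural exchange detection: boundary passages move exactly one
  ## metabolite with coefficient -1 and are never the objective
  single <- vapply(stoich[rxn$id], function(co)
    length(co) == 1L && co[[1]] == -1, logical(1))
  rxn$exchange <- single & rxn$objective == 0
  extIds <- unique(unlist(lapply(stoich[rxn$id[rxn$exchange]], names)))
  met$compartment[met$id %in% extIds] <- "external"
  ## drop metabolites never referenced (dangling species)
  used <- unique(unlist(lapply(stoich, names)))
  met <- met[met$id %in% used, , drop = FALSE]

  MetabolicModel(xml2::xml_attr(mod, "id"), met, rxn, stoich, biomass)
}

.writeSBML <- function(model, path) {
  met <- model@metabolites; rxn <- model@reactions; S <- model@stoichiometry
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  ln <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0(
      '<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
      'fbc:required="false">'), .sbmlNS[["s"]], .sbmlNS[["fbc"]]),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model@speciesId)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(met))) {
    extra <- ""
    if (!is.na(met$formula[i]))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"',
                                     met$formula[i]))
    if (!is.na(met$charge[i]))
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', met$charge[i]))
    ln <- c(ln, sprintf(paste0(
      '      <species id="%s" name="%s" compartment="%s" ',
      'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"%s/>'),
      met$id[i], esc(met$name[i]),
      if (met$compartment[i] == "external") "e" else "c", extra))
  }
  ln <- c(ln, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_len(nrow(rxn)))
    ln <- c(ln,
      sprintf('      <parameter id="lb_%d" value="%.17g" constant="true"/>',
              j, rxn$lb[j]),
      sprintf('      <parameter id="ub_%d" value="%.17g" constant="true"/>',
              j, rxn$ub[j]))
  ln <- c(ln, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    nz <- which(S[, j] != 0)
    reac <- nz[S[nz, j] < 0]; prod <- nz[S[nz, j] > 0]
    ln <- c(ln, sprintf(paste0(
      '      <reaction id="%s" reversible="%s" fast="false" ',
      'fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">'),
      rxn$id[j], if (rxn$lb[j] < 0) "true" else "false", j, j))
    if (length(reac)) {
      ln <- c(ln, '        <listOfReactants>')
      for (i in reac) ln <- c(ln, sprintf(paste0(
        '          <speciesReference species="%s" stoichiometry="%.17g" ',
        'constant="true"/>'), met$id[i], -S[i, j]))
      ln <- c(ln, '        </listOfReactants>')
    }
    if (length(prod)) {
      ln <- c(ln, '        <listOfProducts>')
      for (i in prod) ln <- c(ln, sprintf(paste0(
        '          <speciesReference species="%s" stoichiometry="%.17g" ',
        'constant="true"/>'), met$id[i], S[i, j]))
      ln <- c(ln, '        </listOfProducts>')
    }
    ln <- c(ln, '      </reaction>')
  }
  ln <- c(ln,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                   'fbc:coefficient="1"/>'), model@biomassId),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(ln, path)
}
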