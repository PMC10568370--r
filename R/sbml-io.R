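# SBML Level 3 + FBC v2 input/output.
#
# Implements the subset of SBML-FBC used by curated constraint-based models:
# species with fbc:chemicalFormula, flux bounds as global parameters
# referenced via fbc:lowerFluxBound/fbc:upperFluxBound, and the active FBC
# objective. Species flagged boundaryCondition="true" are dropped together
# with their stoichiometric references (no steady-state constraint applies
# to them), which leaves exchange reactions with a single participant.

.xattr <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- a[names(a) == name | endsWith(names(a), paste0(":", name))]
  if (length(hit)) unname(hit[[1]]) else NA_character_
}

#' Read a metabolic model from SBML Level 3 with FBC
#'
#' @param path path to an SBML L3 file with FBC v2 annotations.
#' @param biomassReaction optional reaction id overriding the biomass
#'   reaction; by default the reaction carrying the active FBC objective.
#' @return a validated \code{\link{MetabolicModel-class}}.
#' @export
readSBMLModel <- function(path, biomassReaction = NULL) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (length(sp) == 0L) stop("no species found: not an SBML model?")
  spTab <- data.frame(
    id = vapply(sp, .xattr, "", name = "id"),
    name = vapply(sp, .xattr, "", name = "name"),
    formula = vapply(sp, .xattr, "", name = "chemicalFormula"),
    compartment = vapply(sp, .xattr, "", name = "compartment"),
    boundary = vapply(sp, .xattr, "", name = "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  # optional explicit molecular weight carried in the species notes
  spTab$mw <- vapply(sp, function(s) {
    note <- xml2::xml_find_first(s, ".//*[local-name()='p']")
    if (inherits(note, "xml_missing")) return(NA_real_)
    txt <- xml2::xml_text(note)
    m <- regmatches(txt, regexec("mw_g_per_mmol:\\s*([0-9eE+.-]+)", txt))[[1]]
    if (length(m) == 2L) as.numeric(m[2]) else NA_real_
  }, numeric(1))

  pars <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parVal <- stats::setNames(
    vapply(pars, function(p) as.numeric(.xattr(p, "value")), numeric(1)),
    vapply(pars, .xattr, "", name = "id"))

  keep <- !spTab$boundary
  internalIds <- spTab$id[keep]

  rxNodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxNodes) == 0L) stop("no reactions found in SBML model")
  reactions <- list()
  for (rx in rxNodes) {
    rid <- .xattr(rx, "id")
    sto <- numeric()
    for (ref in xml2::xml_find_all(rx, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      s <- .xattr(ref, "species")
      sto[s] <- sum(sto[s], -as.numeric(.xattr(ref, "stoichiometry")), na.rm = TRUE)
    }
    for (ref in xml2::xml_find_all(rx, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      s <- .xattr(ref, "species")
      sto[s] <- sum(sto[s], as.numeric(.xattr(ref, "stoichiometry")), na.rm = TRUE)
    }
    unknown <- setdiff(names(sto), spTab$id)
    if (length(unknown))
      stop(sprintf("reaction '%s' references undeclared species: %s",
                   rid, paste(unknown, collapse = ", ")))
    sto <- sto[names(sto) %in% internalIds]
    lbRef <- .xattr(rx, "lowerFluxBound"); ubRef <- .xattr(rx, "upperFluxBound")
    if (is.na(lbRef) || is.na(ubRef))
      stop(sprintf("reaction '%s' lacks FBC flux bounds", rid))
    if (!lbRef %in% names(parVal) || !ubRef %in% names(parVal))
      stop(sprintf("reaction '%s' references undefined bound parameter", rid))
    reactions[[rid]] <- list(stoichiometry = sto,
                             lb = parVal[[lbRef]], ub = parVal[[ubRef]])
  }

  fluxObj <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  objective <- NULL
  if (length(fluxObj)) {
    objective <- stats::setNames(
      vapply(fluxObj, function(o) as.numeric(.xattr(o, "coefficient")), numeric(1)),
      vapply(fluxObj, .xattr, "", name = "reaction"))
    objective <- objective[objective != 0]
  }
  if (is.null(biomassReaction)) {
    if (is.null(objective) || length(objective) == 0L)
      stop("no biomass reaction: the model has no FBC objective and no override was given")
    biomassReaction <- names(objective)[which.max(abs(objective))]
  }
  if (!biomassReaction %in% names(reactions))
    stop(sprintf("biomass reaction '%s' not found in the model", biomassReaction))

  mets <- spTab[keep, c("id", "name", "formula", "compartment", "mw")]
  mets$formula[!nzchar(mets$formula) | is.na(mets$formula)] <- NA_character_
  metabolicModel(metabolites = mets, reactions = reactions,
                 objective = objective, biomassReaction = biomassReaction)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a metabolic model as SBML Level 3 with FBC
#'
#' Emits the same SBML-FBC subset that \code{\link{readSBMLModel}} consumes;
#' a written model re-reads element-wise identically. General linear
#' constraints (\code{A r <= b}) have no SBML representation and are not
#' written. Explicit molecular weights of pseudo-metabolites are carried in
#' the species notes.
#'
#' @param model a \code{\link{MetabolicModel-class}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSBMLModel <- function(model, path) {
  mets <- model@metabolites
  rxns <- reactionIds(model)
  S <- model@stoichiometry
  comps <- unique(mets$compartment)
  comps[is.na(comps)] <- "c"
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', unique(comps)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    attrs <- sprintf('id="%s" compartment="%s" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"',
                     mets$id[i],
                     ifelse(is.na(mets$compartment[i]), "c", mets$compartment[i]))
    if (!is.na(mets$name[i]))
      attrs <- paste0(attrs, sprintf(' name="%s"', .xmlEscape(mets$name[i])))
    if (!is.na(mets$formula[i]))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', mets$formula[i]))
    if (!is.na(mets$mw[i])) {
      out <- c(out, sprintf('      <species %s>', attrs),
               '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
               sprintf('          <p>mw_g_per_mmol: %s</p>', .num(mets$mw[i])),
               '        </body></notes>',
               '      </species>')
    } else {
      out <- c(out, sprintf('      <species %s/>', attrs))
    }
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_along(rxns)) {
    out <- c(out,
      sprintf('      <parameter id="bnd_lb_%d" value="%s" constant="true"/>', j, .num(model@lowerBounds[j])),
      sprintf('      <parameter id="bnd_ub_%d" value="%s" constant="true"/>', j, .num(model@upperBounds[j])))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_along(rxns)) {
    sto <- S[, j]
    sto <- sto[sto != 0]
    out <- c(out, sprintf('      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="bnd_lb_%d" fbc:upperFluxBound="bnd_ub_%d">',
                          rxns[j], tolower(model@lowerBounds[j] < 0), j, j))
    rea <- sto[sto < 0]; pro <- sto[sto > 0]
    if (length(rea)) {
      out <- c(out, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                names(rea), .num(-as.numeric(rea))),
        '        </listOfReactants>')
    }
    if (length(pro)) {
      out <- c(out, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                names(pro), .num(as.numeric(pro))),
        '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  obj <- model@objective[model@objective != 0]
  if (length(obj)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
              names(obj), .num(as.numeric(obj))),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}
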