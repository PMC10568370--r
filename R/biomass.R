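# Biomass reaction introspection and restructuring.

.GAM_ROLES <- c("atp", "adp", "h2o", "pi", "h")
.GAM_SIGNS <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)

# Resolve the five GAM metabolites in the biomass reaction's compartment.
# Conventional id stems (BiGG style "atp_c", "h2o[c]", plain "atp") are
# tried; explicit overrides win.
.resolveGamIds <- function(model, overrides = NULL) {
  mets <- model@metabolites
  br <- model@biomassReaction
  st <- model@stoichiometry[, br]
  inBiomass <- names(st)[st != 0]
  comp <- mets$compartment[match(inBiomass, mets$id)]
  comp <- comp[!is.na(comp)]
  mainComp <- if (length(comp)) names(sort(table(comp), decreasing = TRUE))[1] else NA
  out <- stats::setNames(rep(NA_character_, 5L), .GAM_ROLES)
  for (role in .GAM_ROLES) {
    if (!is.null(overrides) && role %in% names(overrides)) {
      id <- overrides[[role]]
      if (!id %in% mets$id)
        stop(sprintf("GAM override '%s' for role %s is not a model metabolite", id, role))
      out[role] <- id
      next
    }
    pat <- sprintf("^%s([_\\[][A-Za-z0-9\\]]+)?$", role)
    cand <- mets$id[grepl(pat, mets$id, ignore.case = TRUE)]
    if (length(cand) > 1L && !is.na(mainComp)) {
      inMain <- cand[mets$compartment[match(cand, mets$id)] %in% mainComp]
      if (length(inMain)) cand <- inMain
    }
    if (length(cand)) out[role] <- cand[1]
  }
  out
}

#' Extract biomass composition and GAM specification from a model
#'
#' Enumerates the biomass components with their coefficients and molecular
#' weights and splits off the growth-associated maintenance (GAM) part: the
#' GAM value g is read off as the ADP coefficient of the biomass reaction
#' (ADP is produced only by the embedded ATP hydrolysis), and each of the
#' five GAM metabolites gets c_k = c_k,B + c_k,GAM with |c_k,GAM| = g.
#' Components whose biomass-synthesis part c_k,B is zero (pure GAM
#' carriers) are not listed as adjustable components.
#'
#' @param model a \code{MetabolicModel} with a biomass reaction.
#' @param overrides optional named character mapping roles
#'   (atp/adp/h2o/pi/h) to metabolite ids when the conventional id stems do
#'   not apply.
#' @param g optional explicit GAM value overriding ADP-based detection.
#' @return list with elements \code{spec} (\code{BiomassSpec}) and
#'   \code{gam} (\code{GamSpec}).
#' @export
extractBiomassSpec <- function(model, overrides = NULL, g = NULL) {
  br <- model@biomassReaction
  if (is.na(br)) stop("model has no biomass reaction")
  st <- model@stoichiometry[, br]
  st <- st[st != 0]
  if (length(st) == 0L) stop("biomass reaction is empty")
  gamIds <- .resolveGamIds(model, overrides)
  if (is.null(g)) {
    if (is.na(gamIds[["adp"]]))
      stop("cannot detect GAM: no ADP metabolite resolvable and no explicit g supplied")
    g <- if (gamIds[["adp"]] %in% names(st)) unname(st[gamIds[["adp"]]]) else 0
    if (g < 0)
      stop("cannot detect GAM: biomass ADP coefficient is negative")
  }
  if (g > 0 && anyNA(gamIds))
    stop(sprintf("cannot detect GAM: unresolved role(s) %s (use overrides)",
                 paste(.GAM_ROLES[is.na(gamIds)], collapse = ", ")))
  split <- data.frame(id = names(st), cB = as.numeric(st), cGAM = 0,
                      stringsAsFactors = FALSE)
  roles <- data.frame(role = character(), id = character(), sign = numeric(),
                      stringsAsFactors = FALSE)
  if (g > 0) {
    roles <- data.frame(role = .GAM_ROLES, id = unname(gamIds[.GAM_ROLES]),
                        sign = unname(.GAM_SIGNS[.GAM_ROLES]),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(roles))) {
      id <- roles$id[i]
      cg <- g * roles$sign[i]
      j <- match(id, split$id)
      if (is.na(j)) {
        split <- rbind(split, data.frame(id = id, cB = -cg, cGAM = cg))
      } else {
        split$cGAM[j] <- cg
        split$cB[j] <- split$cB[j] - cg
      }
    }
  }
  comp <- split[abs(split$cB) > 1e-12, , drop = FALSE]
  mw <- vapply(comp$id, function(id)
    tryCatch(.metaboliteMw(model, id), error = function(e) NA_real_),
    numeric(1))
  spec <- methods::new("BiomassSpec",
    components = data.frame(id = comp$id, coefficient = comp$cB, mw = unname(mw),
                            stringsAsFactors = FALSE),
    biomassReaction = br)
  gamSpec <- methods::new("GamSpec", g = g, roles = roles, split = split,
                          gamma = if (g > 0) g else 0)
  list(spec = spec, gam = gamSpec)
}

#' Check the 1-g mass convention of a biomass reaction
#'
#' The biomass coefficients (mmol/gDW) times the molecular weights (g/mmol)
#' of the consumed components must sum to the nominal 1 g of dry weight.
#' GAM does not contribute: ATP hydrolysis is mass balanced, and the
#' components carry the GAM-free coefficients c_k,B.
#'
#' @param spec a \code{BiomassSpec}.
#' @param tolerance warn when the total deviates from 1 g by more than this
#'   (default 5e-3 g; published biomass reactions rarely sum exactly).
#' @return total biomass weight in g/gDW: \eqn{-\sum_k c_{k,B} MW_k}.
#' @export
checkBiomassMass <- function(spec, tolerance = 5e-3) {
  d <- spec@components
  if (any(is.na(d$mw)))
    stop(sprintf("no molecular weight for component(s): %s",
                 paste(d$id[is.na(d$mw)], collapse = ", ")))
  total <- -sum(d$coefficient * d$mw)
  if (abs(total - 1) > tolerance)
    warning(sprintf("biomass weighs %.4f g/gDW (deviates from 1 g by more than %g)",
                    total, tolerance))
  total
}

#' Move GAM out of the biomass reaction into a separate reaction
#'
#' Removes the five GAM terms from the biomass reaction and adds a
#' mass-balanced ATP hydrolysis reaction
#' \eqn{g\,ATP + g\,H_2O \rightarrow g\,ADP + g\,P_i + g\,H^+}. To keep the
#' GAM demand coupled to growth, measure the new reaction's rate equal to
#' the growth rate when building adjustment problems.
#'
#' @param model a \code{MetabolicModel}.
#' @param gam the \code{GamSpec} extracted from it.
#' @param reactionId id for the added reaction.
#' @return list with \code{model} (modified) and \code{reactionId}.
#' @export
gamToSeparateReaction <- function(model, gam, reactionId = "GAM_hydrolysis") {
  if (gam@g == 0)
    stop("GAM already extracted or absent (g = 0)")
  br <- model@biomassReaction
  st <- model@stoichiometry[, br]
  st <- st[st != 0]
  for (i in seq_len(nrow(gam@roles))) {
    id <- gam@roles$id[i]
    cg <- gam@g * gam@roles$sign[i]
    st[id] <- if (id %in% names(st)) st[id] - cg else -cg
  }
  st <- st[abs(st) > 1e-12]
  model <- .setReactionStoichiometry(model, br, st)
  gamSt <- stats::setNames(gam@g * gam@roles$sign, gam@roles$id)
  model <- .addReaction(model, reactionId, gamSt, lb = 0, ub = 1000)
  list(model = model, reactionId = reactionId)
}

#' Lump biomass components into macromolecule pseudo-metabolites
#'
#' Rearranges the biomass reaction: the components of each class (e.g.
#' protein, RNA, phospholipids) are collected into a pseudo-metabolite that
#' enters the biomass reaction with coefficient -1 and is produced by one
#' synthesis reaction carrying the original component stoichiometry; the
#' pseudo-metabolite's molecular weight is therefore the grams of that
#' class per gDW. Optional per-class maintenance ATP hydrolysis is added to
#' the synthesis reaction and subtracted from the biomass reaction's total
#' GAM.
#'
#' @param model a \code{MetabolicModel}.
#' @param classMap named character: component metabolite id -> class name;
#'   must cover every organic biomass component (GAM metabolites excepted).
#' @param classMaintenance named numeric: class name -> mmol ATP/gDW of
#'   synthesis maintenance; the total must not exceed the biomass GAM.
#' @param overrides GAM role overrides passed to
#'   \code{\link{extractBiomassSpec}}.
#' @return the rearranged \code{MetabolicModel}.
#' @export
lumpBiomass <- function(model, classMap, classMaintenance = numeric(),
                        overrides = NULL) {
  ex <- extractBiomassSpec(model, overrides = overrides)
  spec <- ex$spec; gam <- ex$gam
  comp <- spec@components
  gamIds <- gam@roles$id
  organic <- comp[!comp$id %in% gamIds, , drop = FALSE]
  missing <- setdiff(organic$id, names(classMap))
  if (length(missing))
    stop(sprintf("biomass component(s) not assigned to a class: %s",
                 paste(missing, collapse = ", ")))
  classes <- unique(unname(classMap[organic$id]))
  maint <- stats::setNames(numeric(length(classes)), classes)
  maint[names(classMaintenance)] <- classMaintenance
  if (any(maint < 0)) stop("class maintenance values must be non-negative")
  if (sum(maint) > gam@g + 1e-9)
    stop(sprintf("total class maintenance (%.4g) exceeds the biomass GAM (%.4g)",
                 sum(maint), gam@g))
  if (any(is.na(organic$mw)))
    stop(sprintf("no molecular weight for component(s): %s",
                 paste(organic$id[is.na(organic$mw)], collapse = ", ")))
  br <- model@biomassReaction
  comp0 <- model@metabolites$compartment[match(organic$id[1], model@metabolites$id)]
  residualGam <- gam@g - sum(maint)

  # new biomass column: pseudo-metabolites, GAM-role cB parts, residual GAM
  newSt <- stats::setNames(rep(-1, length(classes)), paste0("pseudo_", classes))
  for (i in seq_len(nrow(comp))) {
    if (comp$id[i] %in% gamIds) newSt[comp$id[i]] <- comp$coefficient[i]
  }
  if (residualGam > 1e-12) {
    for (i in seq_len(nrow(gam@roles))) {
      id <- gam@roles$id[i]
      add <- residualGam * gam@roles$sign[i]
      newSt[id] <- if (id %in% names(newSt)) newSt[id] + add else add
    }
  }
  newSt <- newSt[abs(newSt) > 1e-12]

  pseudoMets <- data.frame(
    id = paste0("pseudo_", classes),
    name = paste0("lumped ", classes),
    formula = NA_character_, compartment = comp0,
    mw = vapply(classes, function(cl) {
      k <- organic[unname(classMap[organic$id]) == cl, , drop = FALSE]
      sum(-k$coefficient * k$mw)
    }, numeric(1)),
    stringsAsFactors = FALSE)

  out <- model
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    k <- organic[unname(classMap[organic$id]) == cl, , drop = FALSE]
    st <- stats::setNames(k$coefficient, k$id)
    st[paste0("pseudo_", cl)] <- 1
    if (maint[[cl]] > 0) {
      for (i in seq_len(nrow(gam@roles))) {
        id <- gam@roles$id[i]
        add <- maint[[cl]] * gam@roles$sign[i]
        st[id] <- if (id %in% names(st)) st[id] + add else add
      }
    }
    out <- .addReaction(out, paste0("synth_", cl), st, lb = 0, ub = 1000,
                        newMetabolites = pseudoMets[ci, , drop = FALSE])
  }
  .setReactionStoichiometry(out, br, newSt)
}
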