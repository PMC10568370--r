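# Constructors for models and measurement sets.

#' Construct a metabolic model
#'
#' Assembles a \code{\link{MetabolicModel-class}} from a metabolite table and
#' a reaction list. Consumed species carry negative stoichiometric
#' coefficients, produced species positive (SBML convention).
#'
#' @param metabolites data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{formula} (Hill notation), \code{compartment},
#'   \code{mw} (explicit molecular weight, g/mmol).
#' @param reactions named list; each element is a list with
#'   \code{stoichiometry} (named numeric, metabolite id -> coefficient),
#'   \code{lb}, \code{ub} (default \code{-1000}/\code{1000}).
#' @param objective named numeric objective coefficients (default: 1 on the
#'   biomass reaction).
#' @param biomassReaction id of the biomass reaction, or \code{NA}.
#' @param constraints optional list \code{(A, b)} adding general linear
#'   constraints \eqn{A r \le b}; columns of \code{A} follow the reaction
#'   order.
#' @return a validated \code{MetabolicModel}.
#' @export
metabolicModel <- function(metabolites, reactions, objective = NULL,
                           biomassReaction = NA_character_,
                           constraints = list(A = NULL, b = numeric())) {
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  metabolites$id <- as.character(metabolites$id)
  for (col in c("name", "formula", "compartment")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
    metabolites[[col]] <- as.character(metabolites[[col]])
  }
  if (is.null(metabolites$mw)) metabolites$mw <- NA_real_
  rids <- names(reactions)
  if (is.null(rids) || any(!nzchar(rids)))
    stop("reactions must be a named list")
  mids <- metabolites$id
  S <- Matrix::Matrix(0, nrow = length(mids), ncol = length(rids),
                      dimnames = list(mids, rids), sparse = TRUE)
  lb <- ub <- numeric(length(rids))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    st <- rx$stoichiometry
    unknown <- setdiff(names(st), mids)
    if (length(unknown))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   rids[j], paste(unknown, collapse = ", ")))
    S[names(st), j] <- as.numeric(st)
    lb[j] <- if (is.null(rx$lb)) -1000 else rx$lb
    ub[j] <- if (is.null(rx$ub)) 1000 else rx$ub
  }
  names(lb) <- names(ub) <- rids
  if (is.null(objective)) {
    objective <- stats::setNames(numeric(length(rids)), rids)
    if (!is.na(biomassReaction)) objective[biomassReaction] <- 1
  } else {
    obj <- stats::setNames(numeric(length(rids)), rids)
    obj[names(objective)] <- as.numeric(objective)
    objective <- obj
  }
  methods::new("MetabolicModel",
    metabolites = metabolites,
    stoichiometry = methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix"),
    lowerBounds = lb, upperBounds = ub, objective = objective,
    biomassReaction = as.character(biomassReaction),
    constraints = constraints)
}

#' Construct a measurement set
#'
#' @param reactions character vector of reaction ids.
#' @param values measured rates, mmol/(gDW h) (1/h for the growth rate).
#' @param sd optional standard deviations; \code{NA} means not available,
#'   \code{0} means exact (the rate is hard-fixed and receives no
#'   correction variable).
#' @return a \code{\link{MeasurementSet-class}}.
#' @export
measurementSet <- function(reactions, values, sd = NA_real_) {
  d <- data.frame(reaction = as.character(reactions),
                  value = as.numeric(values),
                  sd = rep_len(as.numeric(sd), length(reactions)),
                  stringsAsFactors = FALSE)
  methods::new("MeasurementSet", data = d)
}

# Validate a measurement set against a model: ids must exist and measured
# reactions must not already have fixed bounds (lb == ub), because fixed
# rates are handled through the measurement machinery itself.
.checkMeasurementsAgainstModel <- function(model, meas) {
  d <- measurements(meas)
  unknown <- setdiff(d$reaction, reactionIds(model))
  if (length(unknown))
    stop(sprintf("measured reaction(s) not in the model: %s",
                 paste(unknown, collapse = ", ")))
  fixed <- d$reaction[model@lowerBounds[d$reaction] == model@upperBounds[d$reaction]]
  if (length(fixed))
    stop(sprintf(paste("reaction(s) with fixed model bounds (lb == ub) cannot",
                       "also be measured: %s"), paste(fixed, collapse = ", ")))
  invisible(TRUE)
}

# Reactions touching any species with a single participant are exchanges;
# used by the diagnostics module.
.isExchange <- function(model) {
  Matrix::colSums(model@stoichiometry != 0) == 1L
}

# Replace one column of the stoichiometric matrix (named numeric, full
# replacement) and return the modified model.
.setReactionStoichiometry <- function(model, rid, st) {
  S <- model@stoichiometry
  S[, rid] <- 0
  if (length(st)) S[names(st), rid] <- as.numeric(st)
  model@stoichiometry <- methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
  methods::validObject(model)
  model
}

# Append a reaction column (and any new metabolite rows).
.addReaction <- function(model, rid, st, lb = -1000, ub = 1000,
                         newMetabolites = NULL) {
  if (rid %in% reactionIds(model))
    stop(sprintf("reaction '%s' already exists", rid))
  mets <- model@metabolites
  if (!is.null(newMetabolites)) {
    for (col in c("name", "formula", "compartment"))
      if (is.null(newMetabolites[[col]])) newMetabolites[[col]] <- NA_character_
    if (is.null(newMetabolites$mw)) newMetabolites$mw <- NA_real_
    mets <- rbind(mets, newMetabolites[, names(mets)])
  }
  S <- model@stoichiometry
  newRows <- setdiff(mets$id, rownames(S))
  if (length(newRows)) {
    pad <- Matrix::Matrix(0, length(newRows), ncol(S),
                          dimnames = list(newRows, colnames(S)), sparse = TRUE)
    S <- rbind(S, pad)
  }
  col <- Matrix::Matrix(0, nrow(S), 1, dimnames = list(rownames(S), rid),
                        sparse = TRUE)
  col[names(st), 1] <- as.numeric(st)
  S <- cbind(S, col)
  A <- model@constraints$A
  if (!is.null(A)) {
    A <- cbind(A, 0)
    colnames(A) <- colnames(S)
  }
  methods::new("MetabolicModel",
    metabolites = mets,
    stoichiometry = methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix"),
    lowerBounds = c(model@lowerBounds, stats::setNames(lb, rid)),
    upperBounds = c(model@upperBounds, stats::setNames(ub, rid)),
    objective = c(model@objective, stats::setNames(0, rid)),
    biomassReaction = model@biomassReaction,
    constraints = list(A = A, b = model@constraints$b))
}
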