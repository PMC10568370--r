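# Pre-flight diagnostics: elemental bookkeeping over measured rates,
# FVA range checks, constrained maximum growth.

.formulaCounts <- function(model, id) {
  f <- model@metabolites$formula[match(id, model@metabolites$id)]
  if (is.na(f) || !nzchar(f))
    stop(sprintf("metabolite '%s' has no chemical formula", id))
  parseFormula(f)
}

#' Elemental content of the biomass
#'
#' Mmol of each element incorporated per gram dry weight, computed from the
#' GAM-free component coefficients: content_e = -sum_k c_k,B * count_e(k).
#' GAM terms are excluded because ATP hydrolysis is elementally balanced.
#'
#' @param model the \code{MetabolicModel} (for the formulas).
#' @param spec a \code{BiomassSpec}.
#' @return named numeric, element -> mmol/gDW.
#' @export
biomassElementalContent <- function(model, spec) {
  d <- spec@components
  counts <- lapply(d$id, .formulaCounts, model = model)
  elements <- unique(unlist(lapply(counts, names)))
  content <- stats::setNames(numeric(length(elements)), elements)
  for (k in seq_len(nrow(d))) {
    ce <- counts[[k]]
    content[names(ce)] <- content[names(ce)] - d$coefficient[k] * as.numeric(ce)
  }
  content
}

#' Elemental balance over the measured fluxes
#'
#' For each element occurring in the involved formulas, the net rate in
#' mmol/(gDW h) of elemental matter entering the system through the
#' measured exchange fluxes minus what the biomass drain consumes at the
#' measured growth rate. A positive net is a surplus, a negative net a
#' shortage. Measured internal reactions (neither exchange nor biomass) are
#' excluded with a warning.
#'
#' @param model a \code{MetabolicModel} with formulas on the exchanged
#'   species and biomass components.
#' @param measurements a \code{MeasurementSet}.
#' @param spec optional \code{BiomassSpec} (extracted when omitted and the
#'   growth rate is measured).
#' @return an \code{\link{ElementalBalanceReport-class}}.
#' @export
elementalBalance <- function(model, measurements, spec = NULL) {
  .checkMeasurementsAgainstModel(model, measurements)
  d <- measurements(measurements)
  br <- model@biomassReaction
  exch <- .isExchange(model)
  mu <- 0
  if (!is.na(br) && br %in% d$reaction) {
    mu <- d$value[match(br, d$reaction)]
    if (is.null(spec)) spec <- extractBiomassSpec(model)$spec
  }
  content <- if (mu != 0) biomassElementalContent(model, spec) else
    stats::setNames(numeric(0), character(0))

  contrib <- list()
  for (i in seq_len(nrow(d))) {
    rid <- d$reaction[i]
    if (!is.na(br) && rid == br) next
    if (!exch[[rid]]) {
      warning(sprintf("measured reaction '%s' is neither an exchange nor the biomass reaction; excluded from the elemental balance", rid))
      next
    }
    sto <- model@stoichiometry[, rid]
    sId <- names(sto)[sto != 0]
    # contribution to d(species)/dt, i.e. the rate at which the species
    # (and its elements) enters the system: coefficient * flux
    rate <- as.numeric(sto[sId]) * d$value[i]
    contrib[[rid]] <- rate * .formulaCounts(model, sId)
  }
  elements <- unique(c(names(content), unlist(lapply(contrib, names))))
  M <- matrix(0, length(elements), length(contrib) + (mu != 0),
              dimnames = list(elements,
                              c(names(contrib), if (mu != 0) br)))
  for (rid in names(contrib))
    M[names(contrib[[rid]]), rid] <- contrib[[rid]]
  if (mu != 0) M[names(content), br] <- -mu * content
  methods::new("ElementalBalanceReport",
    net = stats::setNames(rowSums(M), elements),
    contributions = M,
    biomassContent = content)
}

#' Flux variability pre-check for measured rates
#'
#' Runs a flux variability analysis (FVA) over the model constraints alone
#' (steady state, bounds, general constraints; the measurements are NOT
#' fixed) and flags whether each measured value lies inside its feasible
#' range. Ranges open towards an artificial bound are reported as
#' +/-infinity.
#'
#' @param model a \code{MetabolicModel}.
#' @param measurements a \code{MeasurementSet}.
#' @param tol closed-interval tolerance for the in-range flag.
#' @return data.frame: reaction, value, min, max, inRange.
#' @export
fvaPrecheck <- function(model, measurements, tol = 1e-9) {
  .checkMeasurementsAgainstModel(model, measurements)
  d <- measurements(measurements)
  res <- data.frame(reaction = d$reaction, value = d$value,
                    min = NA_real_, max = NA_real_, inRange = NA)
  for (i in seq_len(nrow(d))) {
    rid <- d$reaction[i]
    lo <- .fba(model, objective = stats::setNames(1, rid), maximize = FALSE)
    hi <- .fba(model, objective = stats::setNames(1, rid), maximize = TRUE)
    vlo <- if (lo$status == "unbounded") -Inf
           else if (lo$status == "optimal") lo$fluxes[[rid]]
           else stop(sprintf("FVA subproblem failed for '%s' (%s)", rid, lo$status))
    vhi <- if (hi$status == "unbounded") Inf
           else if (hi$status == "optimal") hi$fluxes[[rid]]
           else stop(sprintf("FVA subproblem failed for '%s' (%s)", rid, hi$status))
    res$min[i] <- vlo; res$max[i] <- vhi
    res$inRange[i] <- d$value[i] >= vlo - tol && d$value[i] <= vhi + tol
  }
  res
}

#' Maximum growth rate under a subset of measurements
#'
#' FBA maximum of the biomass reaction with the given measurements
#' hard-fixed (the subset must not contain the growth reaction itself).
#'
#' @param model a \code{MetabolicModel} with a biomass reaction.
#' @param measurements optional \code{MeasurementSet} to fix; \code{NULL}
#'   gives the plain FBA optimum.
#' @param exclude reaction ids to drop from the measurement set first.
#' @return list with \code{status} ("optimal"/"infeasible"/...) and
#'   \code{growth} (1/h, \code{NA} unless optimal).
#' @export
maxGrowth <- function(model, measurements = NULL, exclude = character()) {
  br <- model@biomassReaction
  if (is.na(br)) stop("model has no biomass reaction")
  fixed <- NULL
  if (!is.null(measurements)) {
    d <- measurements(measurements)
    d <- d[!d$reaction %in% c(br, exclude), , drop = FALSE]
    if (nrow(d)) fixed <- stats::setNames(d$value, d$reaction)
  }
  res <- .fba(model, objective = stats::setNames(1, br), fixed = fixed,
              maximize = TRUE)
  list(status = res$status,
       growth = if (res$status == "optimal") res$objval else NA_real_)
}

#' Sum of component-wise maintenance estimates
#'
#' Adds up per-process growth-associated maintenance estimates (e.g. for
#' DNA, RNA and protein polymerization) into a lower bound for the total
#' GAM demand.
#'
#' @param componentEstimates named numeric, mmol/gDW per process.
#' @return numeric(1), the sum in mmol/gDW.
#' @export
gamLowerBound <- function(componentEstimates) {
  if (length(componentEstimates) == 0L) return(0)
  x <- as.numeric(componentEstimates)
  if (any(!is.finite(x)) || any(x < 0))
    stop("maintenance estimates must be finite and non-negative")
  sum(x)
}
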