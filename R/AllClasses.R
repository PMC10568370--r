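#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Constraint-based metabolic model
#'
#' Container for a stoichiometric model as used in flux balance analysis
#' (FBA): an m x n stoichiometric matrix over internal metabolites, flux
#' bounds per reaction in mmol/(gDW h), an optional block of general linear
#' inequality constraints \eqn{A r \le b}, a linear objective, and the id of
#' the biomass (pseudo) reaction whose flux is the growth rate in 1/h.
#'
#' Metabolites carry optional chemical formulas (Hill notation) and, for
#' pseudo-species such as lumped macromolecules, an optional explicit
#' molecular weight in g/mmol.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula} (character, may be \code{NA}), \code{compartment},
#'   \code{mw} (explicit molecular weight in g/mmol, may be \code{NA}).
#' @slot stoichiometry sparse \code{dgCMatrix}; rows are metabolite ids,
#'   columns reaction ids; consumed species negative, produced positive.
#' @slot lowerBounds,upperBounds named numeric flux bounds per reaction.
#' @slot objective named numeric vector of linear objective coefficients.
#' @slot biomassReaction id of the biomass reaction (\code{NA} if none).
#' @slot constraints list with elements \code{A} (matrix over reactions or
#'   \code{NULL}) and \code{b} (numeric), encoding \eqn{A r \le b}.
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  slots = c(
    metabolites    = "data.frame",
    stoichiometry  = "dgCMatrix",
    lowerBounds    = "numeric",
    upperBounds    = "numeric",
    objective      = "numeric",
    biomassReaction = "character",
    constraints    = "list"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  S <- object@stoichiometry
  rxns <- colnames(S)
  mets <- rownames(S)
  if (is.null(rxns) || is.null(mets))
    msg <- c(msg, "stoichiometry must have metabolite row names and reaction column names")
  if (!identical(sort(object@metabolites$id), sort(mets)))
    msg <- c(msg, "metabolite table and stoichiometry rows disagree")
  for (nm in c("lowerBounds", "upperBounds", "objective")) {
    v <- slot(object, nm)
    if (!identical(names(v), rxns))
      msg <- c(msg, sprintf("%s must be named by the reaction ids, in order", nm))
  }
  if (any(!is.finite(S@x)))
    msg <- c(msg, "stoichiometric coefficients must be finite")
  if (any(is.na(object@lowerBounds)) || any(is.na(object@upperBounds)))
    msg <- c(msg, "bounds must not be NA")
  else if (any(object@lowerBounds > object@upperBounds))
    msg <- c(msg, "lower bound exceeds upper bound for some reaction")
  br <- object@biomassReaction
  if (length(br) != 1L)
    msg <- c(msg, "biomassReaction must be a single id (possibly NA)")
  else if (!is.na(br) && !(br %in% rxns))
    msg <- c(msg, sprintf("biomass reaction '%s' not in the model", br))
  A <- object@constraints$A
  if (!is.null(A)) {
    if (ncol(A) != length(rxns))
      msg <- c(msg, "constraint matrix A must have one column per reaction")
    if (length(object@constraints$b) != nrow(A))
      msg <- c(msg, "constraint vector b must match the rows of A")
  }
  if (length(msg)) msg else TRUE
})

#' Set of measured (fixed) fluxes
#'
#' Measured reaction rates to be imposed on an FBA problem, each optionally
#' with a standard deviation. Entries with \code{sd == 0} are treated as
#' exact (hard-fixed, no correction variable); entries with missing sd fall
#' back to relative weighting.
#'
#' @slot data data.frame with columns \code{reaction}, \code{value}
#'   (mmol/(gDW h), or 1/h for the growth rate) and \code{sd}.
#' @exportClass MeasurementSet
setClass("MeasurementSet", slots = c(data = "data.frame"))

setValidity("MeasurementSet", function(object) {
  d <- object@data
  msg <- character()
  if (!all(c("reaction", "value", "sd") %in% names(d)))
    msg <- c(msg, "data must have columns reaction, value, sd")
  else {
    if (anyDuplicated(d$reaction))
      msg <- c(msg, "duplicated reaction ids in measurement set")
    if (any(!is.finite(d$value)))
      msg <- c(msg, "measured values must be finite")
    if (any(d$sd < 0, na.rm = TRUE))
      msg <- c(msg, "standard deviations must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Biomass reaction composition
#'
#' The biomass components k with their signed stoichiometric coefficients
#' c_k (mmol/gDW; consumed negative) and molecular weights MW_k (g/mmol),
#' after splitting off the growth-associated maintenance (GAM) part: the
#' coefficients stored here are the biomass-synthesis parts c_k,B.
#'
#' @slot components data.frame with columns \code{id}, \code{coefficient}
#'   (c_k,B), \code{mw}.
#' @slot biomassReaction id of the biomass reaction.
#' @exportClass BiomassSpec
setClass("BiomassSpec",
  slots = c(components = "data.frame", biomassReaction = "character"))

setValidity("BiomassSpec", function(object) {
  d <- object@components
  msg <- character()
  if (!all(c("id", "coefficient", "mw") %in% names(d)))
    msg <- c(msg, "components must have columns id, coefficient, mw")
  else {
    if (any(d$coefficient == 0))
      msg <- c(msg, "biomass components must have non-zero coefficients")
    if (any(d$mw <= 0, na.rm = TRUE))
      msg <- c(msg, "molecular weights must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Growth-associated maintenance (GAM) specification
#'
#' GAM is the ATP hydrolysis demand (ATP + H2O -> ADP + Pi + H+) embedded in
#' the biomass reaction, scaled by g mmol ATP per gDW. For each of the five
#' GAM metabolites the biomass coefficient decomposes as
#' c_k = c_k,B + c_k,GAM with |c_k,GAM| = g; ATP and H2O carry sign -1
#' (consumed), ADP, Pi and H+ sign +1 (produced). gamma is the maximal
#' allowed change of g during adjustment (gamma <= g).
#'
#' @slot g GAM value in mmol ATP/gDW (0 when no GAM is present).
#' @slot roles data.frame with columns \code{role} (atp/adp/h2o/pi/h),
#'   \code{id} (metabolite id), \code{sign} (-1 or +1).
#' @slot split data.frame with columns \code{id}, \code{cB}, \code{cGAM}.
#' @slot gamma maximal allowed GAM change in mmol/gDW.
#' @exportClass GamSpec
setClass("GamSpec",
  slots = c(g = "numeric", roles = "data.frame", split = "data.frame",
            gamma = "numeric"))

setValidity("GamSpec", function(object) {
  msg <- character()
  g <- object@g
  if (length(g) != 1L || !is.finite(g) || g < 0)
    msg <- c(msg, "g must be a single non-negative number")
  if (g > 0) {
    r <- object@roles
    if (!setequal(r$role, c("atp", "adp", "h2o", "pi", "h")))
      msg <- c(msg, "roles must cover atp, adp, h2o, pi, h")
    if (!all(r$sign %in% c(-1, 1)))
      msg <- c(msg, "role signs must be -1 or +1")
    want <- ifelse(r$role %in% c("atp", "h2o"), -1, 1)
    if (!all(r$sign == want))
      msg <- c(msg, "ATP and H2O must be consumed (-1); ADP, Pi, H+ produced (+1)")
    s <- object@split
    gm <- s$cGAM[match(r$id, s$id)]
    if (any(abs(abs(gm) - g) > 1e-9 * max(1, g)))
      msg <- c(msg, "|cGAM| must equal g for every GAM metabolite")
    gam <- object@gamma
    if (length(gam) != 1L || !(gam > 0) || gam > g + 1e-12)
      msg <- c(msg, "gamma must satisfy 0 < gamma <= g")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the adjustment problem
#'
#' Selects the adjustment classes (flux corrections, biomass-component
#' adjustment, GAM adjustment), the LP or QP formulation and the weighting
#' schemes.
#'
#' @slot mode "lp" (minimize weighted absolute corrections via split slack
#'   variables) or "qp" (minimize weighted squared corrections).
#' @slot adjustFluxes,adjustBiomass,adjustGam logical flags enabling the
#'   three adjustment classes.
#' @slot fluxWeightScheme "sd_reciprocal" (w_i = 1/sd_i), "relative"
#'   (w_i = 1/|f_i|) or "custom".
#' @slot fluxScale positive scale factor; flux weights are divided by it, so
#'   lowering it makes flux corrections more expensive.
#' @slot fluxWeights named numeric custom weights (scheme "custom").
#' @slot sdSquared use w_i = 1/sd_i^2 instead of 1/sd_i under
#'   "sd_reciprocal".
#' @slot biomassWeightScheme "relative_molar" (z_k from 1/|c_k|),
#'   "relative_mass" (z_k from MW_k) or "custom".
#' @slot biomassWeights named numeric custom weights per component.
#' @slot gamWeight weight on the normalized GAM slack betaGAM (default 1).
#' @slot maxRelBeta bound |beta_k| <= maxRelBeta * |c_k| (default 0.3).
#' @slot gamMaxChange cap on the allowed GAM change gamma in mmol/gDW; the
#'   effective gamma is min(g, gamMaxChange).
#' @exportClass AdjustmentConfig
setClass("AdjustmentConfig",
  slots = c(
    mode = "character",
    adjustFluxes = "logical", adjustBiomass = "logical", adjustGam = "logical",
    fluxWeightScheme = "character", fluxScale = "numeric",
    fluxWeights = "numeric", sdSquared = "logical",
    biomassWeightScheme = "character", biomassWeights = "numeric",
    gamWeight = "numeric", maxRelBeta = "numeric", gamMaxChange = "numeric"
  )
)

setValidity("AdjustmentConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("lp", "qp"))
    msg <- c(msg, "mode must be 'lp' or 'qp'")
  if (!object@fluxWeightScheme %in% c("sd_reciprocal", "relative", "custom"))
    msg <- c(msg, "unknown flux weight scheme")
  if (!object@biomassWeightScheme %in% c("relative_molar", "relative_mass", "custom"))
    msg <- c(msg, "unknown biomass weight scheme")
  if (!(object@fluxScale > 0))
    msg <- c(msg, "fluxScale must be positive")
  if (!(object@maxRelBeta > 0 && object@maxRelBeta <= 1))
    msg <- c(msg, "maxRelBeta must be in (0, 1]")
  if (object@gamWeight < 0)
    msg <- c(msg, "gamWeight must be non-negative")
  if (!(object@gamMaxChange > 0))
    msg <- c(msg, "gamMaxChange must be positive")
  if (length(msg)) msg else TRUE
})

#' Assembled LP/QP adjustment problem
#'
#' Canonical form produced by \code{\link{buildAdjustmentProblem}}:
#' variables with bounds and (linear or diagonal quadratic) costs, equality
#' block Aeq x = beq and inequality block Ain x <= bin. Solved by
#' \code{\link{solveAdjustmentProblem}}.
#'
#' @slot variables data.frame: \code{name}, \code{lb}, \code{ub},
#'   \code{lcost}, \code{qcost}.
#' @slot Aeq,beq equality constraints.
#' @slot Ain,bin inequality constraints (may be empty).
#' @slot mode "lp" or "qp".
#' @slot meta bookkeeping (index maps, measurement/component tables, gamma,
#'   g, growth rate) used to assemble the \code{BalancingResult}.
#' @exportClass AdjustmentProblem
setClass("AdjustmentProblem",
  slots = c(variables = "data.frame",
            Aeq = "matrix", beq = "numeric",
            Ain = "matrixOrNULL", bin = "numeric",
            mode = "character", meta = "list"))

#' Result of an adjustment solve
#'
#' @slot status "optimal", "infeasible", "unbounded" or "solver_error".
#' @slot objectiveValue minimized objective value (OV).
#' @slot fluxes named flux vector r at the optimum.
#' @slot measurements data.frame per measured reaction: value, sd, hard
#'   flag, weight, delta (correction), adjusted value f_i - delta_i.
#' @slot components data.frame per biomass component: coefficient c_k,
#'   beta_k, adjusted coefficient.
#' @slot betaGam normalized GAM slack in [-1, 1] (NA when GAM adjustment
#'   was off).
#' @slot gamInitial,gamAdjusted GAM before and after adjustment
#'   (g' = g + gamma * betaGam).
#' @slot gamma maximal allowed GAM change used.
#' @slot mode "lp" or "qp".
#' @slot diagnostics list: steady-state residual, mass-conservation
#'   residual, solver details.
#' @exportClass BalancingResult
setClass("BalancingResult",
  slots = c(status = "character", objectiveValue = "numeric",
            fluxes = "numeric", measurements = "data.frame",
            components = "data.frame", betaGam = "numeric",
            gamInitial = "numeric", gamAdjusted = "numeric",
            gamma = "numeric", mode = "character", diagnostics = "list"))

#' Elemental balance over measured fluxes
#'
#' @slot net named numeric: per element, net rate in mmol/(gDW h); positive
#'   means surplus (inflow exceeding outflow plus the biomass drain).
#' @slot contributions matrix elements x measurements of per-element rates.
#' @slot biomassContent named numeric, mmol of each element per gDW biomass.
#' @exportClass ElementalBalanceReport
setClass("ElementalBalanceReport",
  slots = c(net = "numeric", contributions = "matrix",
            biomassContent = "numeric"))

#' Scenario comparison from the guideline workflow
#'
#' @slot scenarios named list; each element has \code{result}
#'   (\code{BalancingResult}), \code{config}, \code{label} and
#'   \code{notes} (character flags such as corrected fluxes at bounds).
#' @slot step0 list of pre-flight artifacts: \code{feasible},
#'   \code{fva} table, \code{elemental} report, \code{ngamWarnings}.
#' @exportClass ScenarioComparison
setClass("ScenarioComparison", slots = c(scenarios = "list", step0 = "list"))
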