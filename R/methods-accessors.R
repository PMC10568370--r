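# Accessors and show methods.

#' @describeIn MetabolicModel-class reaction ids, in matrix column order
#' @param object a \code{MetabolicModel}
#' @aliases reactionIds
#' @export
setMethod("reactionIds", "MetabolicModel",
          function(object) colnames(object@stoichiometry))

#' @describeIn MetabolicModel-class metabolite ids, in matrix row order
#' @aliases metaboliteIds
#' @export
setMethod("metaboliteIds", "MetabolicModel",
          function(object) rownames(object@stoichiometry))

#' @describeIn MetabolicModel-class number of reactions
#' @aliases nReactions
#' @export
setMethod("nReactions", "MetabolicModel",
          function(object) ncol(object@stoichiometry))

#' @describeIn MetabolicModel-class number of (internal) metabolites
#' @aliases nMetabolites
#' @export
setMethod("nMetabolites", "MetabolicModel",
          function(object) nrow(object@stoichiometry))

#' @describeIn MetabolicModel-class the sparse stoichiometric matrix
#' @aliases stoichiometry
#' @export
setMethod("stoichiometry", "MetabolicModel",
          function(object) object@stoichiometry)

#' @describeIn MetabolicModel-class named lower flux bounds
#' @aliases lowerBounds
#' @export
setMethod("lowerBounds", "MetabolicModel", function(object) object@lowerBounds)

#' @describeIn MetabolicModel-class named upper flux bounds
#' @aliases upperBounds
#' @export
setMethod("upperBounds", "MetabolicModel", function(object) object@upperBounds)

#' @describeIn MetabolicModel-class linear objective coefficients
#' @aliases objectiveCoefficients
#' @export
setMethod("objectiveCoefficients", "MetabolicModel",
          function(object) object@objective)

#' @describeIn MetabolicModel-class id of the biomass reaction
#' @aliases biomassReaction
#' @export
setMethod("biomassReaction", "MetabolicModel",
          function(object) object@biomassReaction)

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions\n",
              nMetabolites(object), nReactions(object)))
  if (!is.na(object@biomassReaction))
    cat(sprintf("  biomass reaction: %s\n", object@biomassReaction))
  nC <- if (is.null(object@constraints$A)) 0L else nrow(object@constraints$A)
  if (nC > 0) cat(sprintf("  general constraints: %d rows\n", nC))
})

#' @describeIn MeasurementSet-class the measurement table
#' @param object a \code{MeasurementSet}
#' @aliases measurements
#' @export
setMethod("measurements", "MeasurementSet", function(object) object@data)

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet: %d measured rates\n", nrow(object@data)))
  print(object@data, row.names = FALSE)
})

setMethod("length", "MeasurementSet", function(x) nrow(x@data))

setMethod("show", "BiomassSpec", function(object) {
  cat(sprintf("BiomassSpec for '%s': %d components, mass %.4f g/gDW\n",
              object@biomassReaction, nrow(object@components),
              -sum(object@components$coefficient * object@components$mw,
                   na.rm = TRUE)))
})

setMethod("show", "GamSpec", function(object) {
  if (object@g == 0) {
    cat("GamSpec: no GAM detected (g = 0)\n")
  } else {
    cat(sprintf("GamSpec: g = %.4g mmol ATP/gDW, gamma = %.4g\n",
                object@g, object@gamma))
  }
})

#' @describeIn BalancingResult-class solver status
#' @param object a \code{BalancingResult}
#' @aliases solverStatus
#' @export
setMethod("solverStatus", "BalancingResult", function(object) object@status)

#' @describeIn BalancingResult-class minimized objective value (OV)
#' @aliases objectiveValue
#' @export
setMethod("objectiveValue", "BalancingResult",
          function(object) object@objectiveValue)

#' @describeIn BalancingResult-class named optimal flux vector
#' @aliases fluxes
#' @export
setMethod("fluxes", "BalancingResult", function(object) object@fluxes)

#' @describeIn BalancingResult-class adjusted GAM g' = g + gamma * betaGAM
#' @aliases adjustedGam
#' @export
setMethod("adjustedGam", "BalancingResult", function(object) object@gamAdjusted)

#' @describeIn BalancingResult-class per-component adjustment table
#' @aliases componentAdjustments
#' @export
setMethod("componentAdjustments", "BalancingResult",
          function(object) object@components)

#' @describeIn BalancingResult-class per-measurement adjustment table
#' @export
setMethod("measurements", "BalancingResult", function(object) object@measurements)

setMethod("show", "BalancingResult", function(object) {
  cat(sprintf("BalancingResult (%s): status %s\n",
              toupper(object@mode), object@status))
  if (object@status == "optimal") {
    cat(sprintf("  OV = %.6g\n", object@objectiveValue))
    if (nrow(object@measurements)) {
      nadj <- sum(abs(object@measurements$delta) > 5e-4, na.rm = TRUE)
      cat(sprintf("  measurements corrected: %d of %d\n",
                  nadj, nrow(object@measurements)))
    }
    if (!is.na(object@betaGam))
      cat(sprintf("  GAM: %.4g -> %.4g (betaGAM = %.4g)\n",
                  object@gamInitial, object@gamAdjusted, object@betaGam))
  }
})

setMethod("show", "ElementalBalanceReport", function(object) {
  cat("Elemental balance over measured rates [mmol/(gDW h)]:\n")
  for (e in names(object@net))
    cat(sprintf("  %-2s net %+.4g\n", e, object@net[[e]]))
})

setMethod("show", "ScenarioComparison", function(object) {
  cat(sprintf("ScenarioComparison: %d scenarios\n", length(object@scenarios)))
  for (nm in names(object@scenarios)) {
    sc <- object@scenarios[[nm]]
    ov <- if (sc$result@status == "optimal")
      sprintf("OV %.6g", sc$result@objectiveValue) else sc$result@status
    cat(sprintf("  %-10s %-40s %s\n", nm, sc$label, ov))
  }
})
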