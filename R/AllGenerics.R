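#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))

#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))

#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))

#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))

#' @export
setGeneric("objectiveCoefficients",
           function(object) standardGeneric("objectiveCoefficients"))

#' @export
setGeneric("biomassReaction",
           function(object) standardGeneric("biomassReaction"))

#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @export
setGeneric("adjustedGam", function(object) standardGeneric("adjustedGam"))

#' @export
setGeneric("componentAdjustments",
           function(object) standardGeneric("componentAdjustments"))
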