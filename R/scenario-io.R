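# Scenario files: measured fluxes plus adjustment configuration.

#' Create an adjustment configuration
#'
#' @param mode "qp" (minimize weighted squared corrections) or "lp"
#'   (weighted absolute corrections via split slack variables).
#' @param adjustFluxes,adjustBiomass,adjustGam enable the adjustment
#'   classes: measured-flux corrections, biomass-component coefficients,
#'   GAM value.
#' @param fluxWeightScheme "sd_reciprocal" (w_i = 1/sd_i), "relative"
#'   (w_i = 1/|f_i|), or "custom" (supply \code{fluxWeights}).
#' @param fluxScale positive scale; flux weights are divided by it, so a
#'   smaller scale makes flux corrections relatively more expensive.
#' @param fluxWeights named numeric per-reaction weights for scheme
#'   "custom".
#' @param sdSquared if \code{TRUE}, use w_i = 1/sd_i^2 under
#'   "sd_reciprocal".
#' @param biomassWeightScheme "relative_molar" (z_k = 1/c_k^2 in QP,
#'   1/|c_k| in LP), "relative_mass" (z_k = MW_k^2 / MW_k), or "custom".
#' @param biomassWeights named numeric per-component weights for scheme
#'   "custom".
#' @param gamWeight weight on the normalized GAM slack (default 1).
#' @param maxRelBeta bound on relative component changes,
#'   |beta_k| <= maxRelBeta |c_k| (default 0.3).
#' @param gamMaxChange cap on the GAM change in mmol/gDW; the effective
#'   gamma is min(g, gamMaxChange) (default: no cap beyond g).
#' @return an \code{\link{AdjustmentConfig-class}}.
#' @export
adjustmentConfig <- function(mode = c("qp", "lp"),
                             adjustFluxes = TRUE, adjustBiomass = FALSE,
                             adjustGam = FALSE,
                             fluxWeightScheme = c("sd_reciprocal", "relative", "custom"),
                             fluxScale = 1, fluxWeights = numeric(),
                             sdSquared = FALSE,
                             biomassWeightScheme = c("relative_molar", "relative_mass", "custom"),
                             biomassWeights = numeric(),
                             gamWeight = 1, maxRelBeta = 0.3,
                             gamMaxChange = Inf) {
  methods::new("AdjustmentConfig",
    mode = match.arg(mode),
    adjustFluxes = adjustFluxes, adjustBiomass = adjustBiomass,
    adjustGam = adjustGam,
    fluxWeightScheme = match.arg(fluxWeightScheme),
    fluxScale = fluxScale, fluxWeights = fluxWeights, sdSquared = sdSquared,
    biomassWeightScheme = match.arg(biomassWeightScheme),
    biomassWeights = biomassWeights,
    gamWeight = gamWeight, maxRelBeta = maxRelBeta,
    gamMaxChange = gamMaxChange)
}

.SCENARIO_KEYS <- c("measurements", "mode", "adjust", "gam", "biomass", "weights")

#' Read a measurement/configuration scenario file
#'
#' The file (YAML or JSON, by extension) has the schema:
#' \preformatted{
#' measurements: {<rxn_id>: {value: <num>, sd: <num|null>}}
#' mode: lp|qp
#' adjust: {fluxes: bool, biomass: bool, gam: bool}
#' gam: {max_change: <num>, weight: <num>,
#'       metabolites: {atp: <id>, adp: <id>, h2o: <id>, pi: <id>, h: <id>}}
#' biomass: {max_rel_change: <fraction>}
#' weights: {flux_scheme: sd_reciprocal|relative|custom, flux_scale: <num>,
#'           flux_custom: {<rxn_id>: <num>}, sd_squared: bool,
#'           biomass_scheme: relative_molar|relative_mass|custom,
#'           gam_weight: <num>}
#' }
#' Only \code{measurements} is mandatory; configuration defaults are those
#' of \code{\link{adjustmentConfig}}.
#'
#' @param path scenario file.
#' @param model optional \code{MetabolicModel} used to validate reaction
#'   ids.
#' @return list with \code{measurements} (\code{MeasurementSet}),
#'   \code{config} (\code{AdjustmentConfig}) and \code{gamOverrides}
#'   (named character mapping GAM roles to metabolite ids, possibly empty).
#' @export
readScenario <- function(path, model = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .SCENARIO_KEYS)
  if (length(unknown))
    stop(sprintf("unknown scenario key(s): %s", paste(unknown, collapse = ", ")))
  m <- raw$measurements
  if (is.null(m) || length(m) == 0L) stop("no measurements in scenario file")
  vals <- vapply(m, function(e) as.numeric(e$value), numeric(1))
  sds <- vapply(m, function(e)
    if (is.null(e$sd) || length(e$sd) == 0L) NA_real_ else as.numeric(e$sd),
    numeric(1))
  meas <- measurementSet(names(m), vals, sds)

  w <- raw$weights
  adj <- raw$adjust
  gamBlock <- raw$gam
  pick <- function(x, default) if (is.null(x)) default else x
  config <- adjustmentConfig(
    mode = pick(raw$mode, "qp"),
    adjustFluxes = pick(adj$fluxes, TRUE),
    adjustBiomass = pick(adj$biomass, FALSE),
    adjustGam = pick(adj$gam, FALSE),
    fluxWeightScheme = pick(w$flux_scheme, "sd_reciprocal"),
    fluxScale = pick(w$flux_scale, 1),
    fluxWeights = unlist(pick(w$flux_custom, numeric())),
    sdSquared = pick(w$sd_squared, FALSE),
    biomassWeightScheme = pick(w$biomass_scheme, "relative_molar"),
    gamWeight = pick(w$gam_weight, pick(gamBlock$weight, 1)),
    maxRelBeta = pick(raw$biomass$max_rel_change, 0.3),
    gamMaxChange = pick(gamBlock$max_change, Inf))
  gamOverrides <- unlist(pick(gamBlock$metabolites, character()))
  if (!is.null(model)) .checkMeasurementsAgainstModel(model, meas)
  list(measurements = meas, config = config, gamOverrides = gamOverrides)
}

#' Write a scenario file
#'
#' Inverse of \code{\link{readScenario}} for the measurement block and the
#' commonly tuned configuration entries.
#'
#' @param measurements a \code{MeasurementSet}.
#' @param config an \code{AdjustmentConfig}.
#' @param path output path (.yaml/.yml or .json).
#' @param gamOverrides optional named character role -> metabolite id.
#' @return \code{path}, invisibly.
#' @export
writeScenario <- function(measurements, config, path, gamOverrides = NULL) {
  d <- measurements(measurements)
  mlist <- lapply(seq_len(nrow(d)), function(i) {
    e <- list(value = d$value[i])
    if (!is.na(d$sd[i])) e$sd <- d$sd[i]
    e
  })
  names(mlist) <- d$reaction
  out <- list(
    measurements = mlist,
    mode = config@mode,
    adjust = list(fluxes = config@adjustFluxes,
                  biomass = config@adjustBiomass,
                  gam = config@adjustGam),
    weights = list(flux_scheme = config@fluxWeightScheme,
                   flux_scale = config@fluxScale,
                   sd_squared = config@sdSquared,
                   biomass_scheme = config@biomassWeightScheme,
                   gam_weight = config@gamWeight),
    biomass = list(max_rel_change = config@maxRelBeta))
  gamBlock <- list()
  if (is.finite(config@gamMaxChange)) gamBlock$max_change <- config@gamMaxChange
  if (length(gamOverrides)) gamBlock$metabolites <- as.list(gamOverrides)
  if (length(gamBlock)) out$gam <- gamBlock
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
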