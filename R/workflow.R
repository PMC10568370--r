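# Guideline driver: step 0 diagnostics, step 1 flux-only corrections,
# step 2 biomass/GAM-only, step 3 merged; scenario comparison report.

.UNCHANGED_TOL <- 5e-4  # display threshold matching 2-3 printed decimals

.withConfig <- function(config, mode = NULL, fluxes = NULL, biomass = NULL,
                        gam = NULL) {
  if (!is.null(mode)) config@mode <- mode
  if (!is.null(fluxes)) config@adjustFluxes <- fluxes
  if (!is.null(biomass)) config@adjustBiomass <- biomass
  if (!is.null(gam)) config@adjustGam <- gam
  config
}

.scenarioNotes <- function(result, model, config) {
  if (result@status != "optimal") return(character())
  notes <- character()
  d <- result@measurements
  soft <- d[!d$hard, , drop = FALSE]
  atBound <- soft$reaction[
    abs(soft$adjusted - model@lowerBounds[soft$reaction]) < 1e-7 |
    abs(soft$adjusted - model@upperBounds[soft$reaction]) < 1e-7]
  if (length(atBound))
    notes <- c(notes, sprintf("corrected flux at reaction bound: %s",
                              paste(atBound, collapse = ", ")))
  cp <- result@components
  if (nrow(cp)) {
    lim <- config@maxRelBeta * abs(cp$coefficient)
    hit <- cp$id[abs(abs(cp$beta) - lim) < 1e-7]
    if (length(hit))
      notes <- c(notes, sprintf("component change at the %g%% limit: %s",
                                100 * config@maxRelBeta,
                                paste(hit, collapse = ", ")))
  }
  if (!is.na(result@betaGam) && abs(abs(result@betaGam) - 1) < 1e-7)
    notes <- c(notes, "GAM change hit the allowed maximum gamma")
  notes
}

# Flag lower-bounded ATP-hydrolysis-like reactions (NGAM). The guideline
# suggests relaxing such fixed demands or converting them into adjustable
# measurements.
.ngamWarnings <- function(model, gam) {
  if (is.null(gam) || gam@g == 0 && nrow(gam@roles) == 0) return(character())
  atp <- gam@roles$id[gam@roles$role == "atp"]
  adp <- gam@roles$id[gam@roles$role == "adp"]
  if (!length(atp) || !length(adp)) return(character())
  S <- model@stoichiometry
  hits <- character()
  for (rid in reactionIds(model)) {
    if (identical(rid, model@biomassReaction)) next
    if (model@lowerBounds[[rid]] <= 0) next
    sto <- S[, rid]
    if (atp %in% rownames(S) && adp %in% rownames(S) &&
        sto[atp] < 0 && sto[adp] > 0)
      hits <- c(hits, sprintf(
        "reaction '%s' looks like an NGAM demand (ATP hydrolysis with lower bound %g); consider relaxing the bound or treating it as a measurement",
        rid, model@lowerBounds[[rid]]))
  }
  hits
}

#' Run the staged adjustment guideline
#'
#' Executes the recommended workflow on an infeasible measurement scenario:
#' step 0 pre-flight diagnostics (feasibility with the rates fixed, FVA
#' ranges, elemental balance, NGAM checklist), step 1 flux corrections only
#' (LP and QP), step 2 biomass-side adjustments only (2a GAM, 2b
#' components, 2c both; these can legitimately be infeasible), and step 3
#' flux plus biomass-side adjustments merged. Solver failures in one
#' scenario do not abort the others.
#'
#' @param model a \code{MetabolicModel}, feasible without the measurements.
#' @param measurements a \code{MeasurementSet}.
#' @param config base \code{AdjustmentConfig}; its mode is used for the
#'   merged step, its weights everywhere.
#' @param gamOverrides optional GAM role overrides.
#' @return a \code{\link{ScenarioComparison-class}}.
#' @export
runGuideline <- function(model, measurements, config = adjustmentConfig(),
                         gamOverrides = NULL) {
  .checkMeasurementsAgainstModel(model, measurements)
  d <- measurements(measurements)
  fixedAll <- stats::setNames(d$value, d$reaction)
  feas <- .fba(model, fixed = fixedAll)
  ex <- tryCatch(extractBiomassSpec(model, overrides = gamOverrides),
                 error = function(e) NULL)
  spec <- ex$spec; gam <- ex$gam
  step0 <- list(
    feasible = feas$status == "optimal",
    fva = fvaPrecheck(model, measurements),
    elemental = tryCatch(elementalBalance(model, measurements, spec),
                         error = function(e) NULL,
                         warning = function(w) NULL),
    ngamWarnings = .ngamWarnings(model, gam))

  haveBiomass <- !is.null(ex)
  haveGam <- haveBiomass && gam@g > 0
  plan <- list(
    step1_lp = list(label = "flux corrections only (LP)",
                    cfg = .withConfig(config, "lp", TRUE, FALSE, FALSE)),
    step1_qp = list(label = "flux corrections only (QP)",
                    cfg = .withConfig(config, "qp", TRUE, FALSE, FALSE)))
  if (haveGam)
    plan$step2a <- list(label = "GAM adjustment only",
                        cfg = .withConfig(config, NULL, FALSE, FALSE, TRUE))
  if (haveBiomass)
    plan$step2b <- list(label = "biomass component adjustment only",
                        cfg = .withConfig(config, NULL, FALSE, TRUE, FALSE))
  if (haveGam)
    plan$step2c <- list(label = "biomass component + GAM adjustment",
                        cfg = .withConfig(config, NULL, FALSE, TRUE, TRUE))
  if (haveBiomass)
    plan$step3 <- list(label = sprintf("merged flux + biomass%s adjustment (%s)",
                                       if (haveGam) " + GAM" else "",
                                       toupper(config@mode)),
                       cfg = .withConfig(config, NULL, TRUE, TRUE, haveGam))

  scenarios <- list()
  for (nm in names(plan)) {
    cfg <- plan[[nm]]$cfg
    res <- tryCatch(
      balanceFluxes(model, measurements, spec, gam, cfg),
      error = function(e) methods::new("BalancingResult",
        status = "solver_error", objectiveValue = NA_real_,
        fluxes = stats::setNames(numeric(0), character(0)),
        measurements = d[0, ], components = data.frame(),
        betaGam = NA_real_, gamInitial = NA_real_, gamAdjusted = NA_real_,
        gamma = 0, mode = cfg@mode,
        diagnostics = list(message = conditionMessage(e))))
    scenarios[[nm]] <- list(result = res, config = cfg,
                            label = plan[[nm]]$label,
                            notes = .scenarioNotes(res, model, cfg))
  }
  methods::new("ScenarioComparison", scenarios = scenarios, step0 = step0)
}

#' Render a scenario comparison
#'
#' One row per measured rate (and per reported biomass quantity), one
#' column per scenario; corrections below the display threshold print as
#' "Unchanged", hard-fixed rates as "Fixed". Raw values are always
#' available from the \code{"data.frame"} and \code{"json"} formats.
#'
#' @param comparison a \code{ScenarioComparison}.
#' @param format "data.frame", "tsv", "markdown" or "json".
#' @param digits printed decimals for adjusted values.
#' @return a data.frame, or a character scalar holding the document.
#' @export
renderComparison <- function(comparison,
                             format = c("data.frame", "tsv", "markdown", "json"),
                             digits = 3) {
  format <- match.arg(format)
  scen <- comparison@scenarios
  if (length(scen) == 0L) stop("comparison contains no scenarios")
  first <- NULL
  for (sc in scen) if (sc$result@status == "optimal") { first <- sc$result; break }
  if (is.null(first)) stop("no scenario solved to optimality")
  measIds <- first@measurements$reaction
  compIds <- unique(unlist(lapply(scen, function(sc)
    if (sc$result@status == "optimal") sc$result@components$id else character())))
  rows <- data.frame(quantity = c(measIds, "GAM", compIds, "OV"),
                     stringsAsFactors = FALSE)
  gamInit <- NA_real_
  for (sc in scen)
    if (!is.na(sc$result@gamInitial)) { gamInit <- sc$result@gamInitial; break }
  base <- c(formatC(first@measurements$value, digits = digits, format = "f"),
            if (!is.na(gamInit)) formatC(gamInit, digits = digits, format = "f") else "",
            rep("", length(compIds)), "")
  tab <- data.frame(quantity = rows$quantity, model_value = base,
                    stringsAsFactors = FALSE, check.names = FALSE)
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  for (nm in names(scen)) {
    res <- scen[[nm]]$result
    col <- rep("", nrow(tab))
    if (res@status != "optimal") {
      col[] <- res@status
    } else {
      md <- res@measurements
      for (i in seq_along(measIds)) {
        j <- match(measIds[i], md$reaction)
        col[i] <- if (md$hard[j]) "Fixed"
          else if (abs(md$delta[j]) < .UNCHANGED_TOL) "Unchanged"
          else fmt(md$adjusted[j])
      }
      gi <- length(measIds) + 1L
      col[gi] <- if (!is.na(res@gamAdjusted)) fmt(res@gamAdjusted)
                 else if (!is.na(res@gamInitial)) "Fixed" else ""
      for (k in seq_along(compIds)) {
        j <- match(compIds[k], res@components$id)
        col[gi + k] <- if (is.na(j)) "Fixed"
          else if (abs(res@components$beta[j]) < .UNCHANGED_TOL) "Unchanged"
          else sprintf("%+.2f%%", 100 * res@components$beta[j] /
                                  abs(res@components$coefficient[j]))
      }
      col[nrow(tab)] <- formatC(res@objectiveValue, digits = max(digits, 4),
                                format = "g")
    }
    tab[[nm]] <- col
  }
  switch(format,
    "data.frame" = tab,
    tsv = paste(c(paste(names(tab), collapse = "\t"),
                  apply(tab, 1, paste, collapse = "\t")), collapse = "\n"),
    markdown = {
      hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
      body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      paste(c(hdr, sep, body), collapse = "\n")
    },
    json = as.character(jsonlite::toJSON(tab, dataframe = "rows", digits = NA,
                                         auto_unbox = TRUE)))
}
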