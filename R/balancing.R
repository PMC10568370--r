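# Assembly and solution of the LP/QP adjustment problems.
#
# Decision variables: the full flux vector r; a correction delta_i per
# soft-measured reaction (r_i = f_i - delta_i); a component slack beta_k
# per adjustable biomass component (coefficient becomes c_k + beta_k,
# subject to sum(beta_k MW_k) = 0); and a normalized GAM slack
# betaGAM in [-1, 1] scaling the common change of the five GAM metabolites
# by gamma mmol/gDW. In LP mode each slack is split into a non-negative
# positive/negative pair. Because the biomass component constraints contain
# the product beta_k * mu, the growth rate mu must be hard-fixed whenever
# biomass or GAM adjustment is enabled.

#' Default correction weights for measured fluxes
#'
#' Implements the weighting schemes for flux corrections:
#' \code{"sd_reciprocal"} sets w_i = (1/sd_i)/fluxScale (or 1/sd_i^2 with
#' \code{sdSquared}); \code{"relative"} sets w_i = (1/|f_i|)/fluxScale.
#' Entries that admit no finite weight are "hard": sd = 0 under
#' sd_reciprocal (the measurement is exact), f = 0 under relative. Hard
#' entries are fixed exactly and receive no correction variable. A missing
#' sd under sd_reciprocal falls back to the relative scheme for that entry,
#' with a warning.
#'
#' @param measurements a \code{MeasurementSet}.
#' @param scheme "sd_reciprocal", "relative" or "custom".
#' @param fluxScale positive scale factor dividing all weights.
#' @param sdSquared use 1/sd^2 instead of 1/sd.
#' @param fluxWeights named numeric for scheme "custom"; \code{Inf} marks a
#'   hard entry.
#' @return data.frame with columns reaction, value, sd, weight, hard.
#' @export
defaultFluxWeights <- function(measurements,
                               scheme = c("sd_reciprocal", "relative", "custom"),
                               fluxScale = 1, sdSquared = FALSE,
                               fluxWeights = numeric()) {
  scheme <- match.arg(scheme)
  d <- measurements(measurements)
  d$weight <- NA_real_
  d$hard <- FALSE
  for (i in seq_len(nrow(d))) {
    f <- d$value[i]; s <- d$sd[i]
    if (scheme == "custom") {
      if (!d$reaction[i] %in% names(fluxWeights))
        stop(sprintf("no custom weight for measured reaction '%s'", d$reaction[i]))
      w <- fluxWeights[[d$reaction[i]]]
      if (is.infinite(w)) d$hard[i] <- TRUE else d$weight[i] <- w / fluxScale
      next
    }
    useRelative <- scheme == "relative"
    if (scheme == "sd_reciprocal") {
      if (is.na(s)) {
        warning(sprintf("measurement '%s' has no sd; falling back to relative weighting",
                        d$reaction[i]))
        useRelative <- TRUE
      } else if (s == 0) {
        d$hard[i] <- TRUE
        next
      } else {
        d$weight[i] <- (if (sdSquared) 1 / s^2 else 1 / s) / fluxScale
        next
      }
    }
    if (useRelative) {
      if (f == 0) d$hard[i] <- TRUE
      else d$weight[i] <- (1 / abs(f)) / fluxScale
    }
  }
  d
}

.biomassWeights <- function(spec, mode, scheme, custom = numeric()) {
  d <- spec@components
  switch(scheme,
    relative_molar = if (mode == "qp") 1 / d$coefficient^2 else 1 / abs(d$coefficient),
    relative_mass = {
      if (any(is.na(d$mw)))
        stop(sprintf("relative_mass weighting needs molecular weights; missing for: %s",
                     paste(d$id[is.na(d$mw)], collapse = ", ")))
      if (mode == "qp") d$mw^2 else d$mw
    },
    custom = {
      missing <- setdiff(d$id, names(custom))
      if (length(missing))
        stop(sprintf("no custom biomass weight for component(s): %s",
                     paste(missing, collapse = ", ")))
      as.numeric(custom[d$id])
    })
}

#' Build the LP/QP adjustment problem
#'
#' Assembles the feasibility-restoration program over steady state, flux
#' bounds, general linear constraints, measurement links, biomass-component
#' balances with the mass-conservation constraint, and the GAM rows, with
#' the objective blocks selected by \code{config}.
#'
#' @param model a \code{MetabolicModel}, feasible without the measurements.
#' @param measurements a \code{MeasurementSet}; must contain the growth
#'   rate when biomass or GAM adjustment is enabled (the component
#'   constraints are bilinear in beta and mu otherwise).
#' @param spec,gam biomass composition and GAM specification; extracted
#'   from the model when omitted and needed.
#' @param config an \code{\link{adjustmentConfig}}.
#' @param gamOverrides GAM role overrides used when extracting the spec.
#' @return an \code{\link{AdjustmentProblem-class}}.
#' @export
buildAdjustmentProblem <- function(model, measurements, spec = NULL, gam = NULL,
                                   config = adjustmentConfig(),
                                   gamOverrides = NULL) {
  .checkMeasurementsAgainstModel(model, measurements)
  mode <- config@mode
  needMu <- config@adjustBiomass || config@adjustGam
  if (needMu && (is.null(spec) || is.null(gam))) {
    ex <- extractBiomassSpec(model, overrides = gamOverrides)
    if (is.null(spec)) spec <- ex$spec
    if (is.null(gam)) gam <- ex$gam
  }
  br <- model@biomassReaction
  mu <- NA_real_
  if (needMu) {
    if (is.na(br)) stop("model has no biomass reaction")
    d <- measurements(measurements)
    gi <- match(br, d$reaction)
    if (is.na(gi))
      stop(paste("biomass or GAM adjustment requires the growth rate in the",
                 "measurement set: the component constraints contain the",
                 "product beta * mu, which is bilinear unless mu is fixed"))
    mu <- d$value[gi]
    d$sd[gi] <- 0  # growth is never softened alongside beta (hard-fixed)
    measurements <- methods::new("MeasurementSet", data = d)
  }
  measTab <- if (config@adjustFluxes)
    defaultFluxWeights(measurements, scheme = config@fluxWeightScheme,
                       fluxScale = config@fluxScale,
                       sdSquared = config@sdSquared,
                       fluxWeights = config@fluxWeights)
  else {
    d <- measurements(measurements)
    d$weight <- NA_real_; d$hard <- TRUE
    d
  }
  if (needMu) {
    gi <- match(br, measTab$reaction)
    measTab$hard[gi] <- TRUE
    measTab$weight[gi] <- NA_real_
  }
  gamma <- 0
  if (config@adjustGam) {
    if (gam@g == 0) stop("GAM adjustment requested but the model has no GAM (g = 0)")
    gamma <- min(gam@g, config@gamMaxChange)
  }
  comps <- if (config@adjustBiomass) spec@components else
    data.frame(id = character(), coefficient = numeric(), mw = numeric())
  if (nrow(comps) > 0L && any(is.na(comps$mw)))
    stop(sprintf("mass conservation needs molecular weights; missing for: %s",
                 paste(comps$id[is.na(comps$mw)], collapse = ", ")))
  zk <- if (nrow(comps)) .biomassWeights(spec, mode, config@biomassWeightScheme,
                                         config@biomassWeights) else numeric()

  rxns <- reactionIds(model)
  mets <- metaboliteIds(model)
  n <- length(rxns); m <- length(mets)
  soft <- which(!measTab$hard)
  split <- mode == "lp"

  vname <- rxns
  vlb <- model@lowerBounds; vub <- model@upperBounds
  lcost <- stats::setNames(numeric(n), rxns)
  qcost <- stats::setNames(numeric(n), rxns)
  addVar <- function(name, lb, ub, lc, qc) {
    vname <<- c(vname, name)
    vlb <<- c(vlb, stats::setNames(lb, name))
    vub <<- c(vub, stats::setNames(ub, name))
    lcost <<- c(lcost, stats::setNames(lc, name))
    qcost <<- c(qcost, stats::setNames(qc, name))
  }
  for (i in soft) {
    id <- measTab$reaction[i]; w <- measTab$weight[i]
    if (split) {
      addVar(paste0("deltaP_", id), 0, Inf, w, 0)
      addVar(paste0("deltaM_", id), 0, Inf, w, 0)
    } else addVar(paste0("delta_", id), -Inf, Inf, 0, w)
  }
  for (k in seq_len(nrow(comps))) {
    bk <- config@maxRelBeta * abs(comps$coefficient[k])
    id <- comps$id[k]
    if (split) {
      addVar(paste0("betaP_", id), 0, bk, zk[k], 0)
      addVar(paste0("betaM_", id), 0, bk, zk[k], 0)
    } else addVar(paste0("beta_", id), -bk, bk, 0, zk[k])
  }
  if (config@adjustGam) {
    if (split) {
      addVar("betaGAMp", 0, 1, config@gamWeight, 0)
      addVar("betaGAMm", 0, 1, config@gamWeight, 0)
    } else addVar("betaGAM", -1, 1, 0, config@gamWeight)
  }

  nv <- length(vname)
  nrows <- m + nrow(measTab) + (if (nrow(comps)) 1L else 0L)
  Aeq <- matrix(0, nrows, nv, dimnames = list(NULL, vname))
  beq <- numeric(nrows)
  Aeq[seq_len(m), seq_len(n)] <- as.matrix(model@stoichiometry)
  # beta terms in the component rows; GAM slack in the five GAM rows
  for (k in seq_len(nrow(comps))) {
    row <- match(comps$id[k], mets)
    if (split) {
      Aeq[row, paste0("betaP_", comps$id[k])] <- mu
      Aeq[row, paste0("betaM_", comps$id[k])] <- -mu
    } else Aeq[row, paste0("beta_", comps$id[k])] <- mu
  }
  if (config@adjustGam) {
    for (i in seq_len(nrow(gam@roles))) {
      row <- match(gam@roles$id[i], mets)
      coef <- gamma * gam@roles$sign[i] * mu
      if (split) {
        Aeq[row, "betaGAMp"] <- coef
        Aeq[row, "betaGAMm"] <- -coef
      } else Aeq[row, "betaGAM"] <- coef
    }
  }
  for (i in seq_len(nrow(measTab))) {
    row <- m + i
    Aeq[row, measTab$reaction[i]] <- 1
    if (!measTab$hard[i]) {
      id <- measTab$reaction[i]
      if (split) {
        Aeq[row, paste0("deltaP_", id)] <- 1
        Aeq[row, paste0("deltaM_", id)] <- -1
      } else Aeq[row, paste0("delta_", id)] <- 1
    }
    beq[row] <- measTab$value[i]
  }
  if (nrow(comps)) {
    row <- m + nrow(measTab) + 1L
    for (k in seq_len(nrow(comps))) {
      id <- comps$id[k]
      if (split) {
        Aeq[row, paste0("betaP_", id)] <- comps$mw[k]
        Aeq[row, paste0("betaM_", id)] <- -comps$mw[k]
      } else Aeq[row, paste0("beta_", id)] <- comps$mw[k]
    }
  }
  Ain <- NULL; bin <- numeric()
  A <- model@constraints$A
  if (!is.null(A) && nrow(A) > 0L) {
    Ain <- matrix(0, nrow(A), nv, dimnames = list(NULL, vname))
    Ain[, seq_len(n)] <- as.matrix(A)
    bin <- model@constraints$b
  }
  methods::new("AdjustmentProblem",
    variables = data.frame(name = vname, lb = unname(vlb), ub = unname(vub),
                           lcost = unname(lcost), qcost = unname(qcost),
                           stringsAsFactors = FALSE),
    Aeq = Aeq, beq = beq, Ain = Ain, bin = bin, mode = mode,
    meta = list(rxns = rxns, mets = mets, measTab = measTab,
                comps = comps, split = split, mu = mu, gamma = gamma,
                g = if (config@adjustGam) gam@g else NA_real_,
                gamRoles = if (config@adjustGam) gam@roles else NULL,
                adjustGam = config@adjustGam))
}

#' Solve an adjustment problem
#'
#' Dispatches to the LP (simplex) or convex-QP (Goldfarb-Idnani) backend
#' and assembles a \code{\link{BalancingResult-class}}. A non-optimal
#' status is reported as such; a solution is never returned silently from a
#' failed solve.
#'
#' @param problem an \code{\link{AdjustmentProblem-class}}.
#' @return a \code{BalancingResult}.
#' @export
solveAdjustmentProblem <- function(problem) {
  v <- problem@variables
  meta <- problem@meta
  sol <- if (problem@mode == "lp")
    .solveCanonicalLP(stats::setNames(v$lcost, v$name), problem@Aeq,
                      problem@beq, problem@Ain, problem@bin, v$lb, v$ub)
  else
    .solveCanonicalQP(stats::setNames(v$lcost, v$name),
                      stats::setNames(v$qcost, v$name), problem@Aeq,
                      problem@beq, problem@Ain, problem@bin, v$lb, v$ub)
  measTab <- meta$measTab
  emptyMeas <- measTab[0, ]
  if (sol$status != "optimal") {
    return(methods::new("BalancingResult",
      status = sol$status, objectiveValue = NA_real_,
      fluxes = stats::setNames(numeric(0), character(0)),
      measurements = emptyMeas, components = meta$comps[0, ],
      betaGam = NA_real_, gamInitial = meta$g, gamAdjusted = NA_real_,
      gamma = meta$gamma, mode = problem@mode,
      diagnostics = list(message = sol$message, gamRoles = meta$gamRoles)))
  }
  x <- sol$x
  r <- x[meta$rxns]
  measTab$delta <- measTab$value - unname(r[measTab$reaction])
  measTab$adjusted <- unname(r[measTab$reaction])
  comps <- meta$comps
  if (nrow(comps)) {
    comps$beta <- vapply(comps$id, function(id) {
      if (meta$split) unname(x[paste0("betaP_", id)] - x[paste0("betaM_", id)])
      else unname(x[paste0("beta_", id)])
    }, numeric(1))
    comps$adjusted <- comps$coefficient + comps$beta
  } else {
    comps$beta <- numeric(0); comps$adjusted <- numeric(0)
  }
  betaGam <- NA_real_; gAdj <- NA_real_
  if (isTRUE(meta$adjustGam)) {
    betaGam <- if (meta$split) unname(x["betaGAMp"] - x["betaGAMm"])
               else unname(x["betaGAM"])
    gAdj <- meta$g + meta$gamma * betaGam
  }
  S <- problem@Aeq[seq_along(meta$mets), , drop = FALSE]
  ssResidual <- max(abs(S %*% x))
  massResidual <- if (nrow(comps)) sum(comps$beta * comps$mw) else 0
  methods::new("BalancingResult",
    status = "optimal", objectiveValue = max(0, sol$objval),
    fluxes = r, measurements = measTab, components = comps,
    betaGam = betaGam, gamInitial = meta$g, gamAdjusted = gAdj,
    gamma = meta$gamma, mode = problem@mode,
    diagnostics = list(steadyStateResidual = ssResidual,
                       massResidual = massResidual,
                       gamRoles = meta$gamRoles, message = sol$message))
}

#' Build and solve in one call
#'
#' @inheritParams buildAdjustmentProblem
#' @return a \code{BalancingResult}.
#' @export
balanceFluxes <- function(model, measurements, spec = NULL, gam = NULL,
                          config = adjustmentConfig(), gamOverrides = NULL) {
  solveAdjustmentProblem(
    buildAdjustmentProblem(model, measurements, spec, gam, config,
                           gamOverrides = gamOverrides))
}

#' Recover biomass-coefficient perturbations from a fixed flux vector
#'
#' With every reaction rate hard-fixed to \code{fluxVector}, the
#' steady-state row of each biomass component determines its slack beta_k
#' pointwise; if the model's biomass was perturbed mass-neutrally by
#' Delta_k relative to the stoichiometry that generated the fluxes, the
#' solve returns beta_k = -Delta_k.
#'
#' @param model the (perturbed) \code{MetabolicModel}.
#' @param fluxVector named numeric covering every reaction, a flux
#'   distribution feasible for the unperturbed stoichiometry.
#' @param spec,gam optional pre-extracted biomass/GAM specification.
#' @param config configuration; biomass adjustment is forced on and flux
#'   corrections off.
#' @return a \code{BalancingResult}.
#' @export
recoverBiomassPerturbation <- function(model, fluxVector, spec = NULL,
                                       gam = NULL,
                                       config = adjustmentConfig()) {
  missing <- setdiff(reactionIds(model), names(fluxVector))
  if (length(missing))
    stop(sprintf("fluxVector must fix every reaction; missing: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  meas <- measurementSet(names(fluxVector), as.numeric(fluxVector), sd = 0)
  config@adjustFluxes <- FALSE
  config@adjustBiomass <- TRUE
  balanceFluxes(model, meas, spec, gam, config)
}

#' Write adjusted biomass coefficients back into a model
#'
#' Applies the component slacks beta_k and the GAM change
#' gamma * sign(c_k,GAM) * betaGAM to the biomass reaction. Measured-flux
#' adjustments are data, not model properties, and are not written.
#'
#' @param model the model the result was computed for.
#' @param result an optimal \code{BalancingResult}.
#' @return the adjusted \code{MetabolicModel}.
#' @export
applyResult <- function(model, result) {
  if (result@status != "optimal")
    stop("cannot apply a non-optimal result")
  br <- model@biomassReaction
  st <- model@stoichiometry[, br]
  st <- st[st != 0]
  comps <- result@components
  for (k in seq_len(nrow(comps))) {
    id <- comps$id[k]
    st[id] <- (if (id %in% names(st)) st[id] else 0) + comps$beta[k]
  }
  if (!is.na(result@betaGam) && result@gamma > 0) {
    roles <- result@diagnostics$gamRoles
    for (i in seq_len(nrow(roles))) {
      id <- roles$id[i]
      add <- result@gamma * roles$sign[i] * result@betaGam
      st[id] <- (if (id %in% names(st)) st[id] else 0) + add
    }
  }
  st <- st[abs(st) > 1e-12]
  .setReactionStoichiometry(model, br, st)
}

#' Range of a reported quantity over the optimal face (LP)
#'
#' LP optima need not be unique. At the minimized objective value (within a
#' relative tolerance), this post-pass minimizes and maximizes a named
#' quantity, reporting the interval it can take among optimal solutions.
#' QP optima are unique in the correction variables, so the point value is
#' returned.
#'
#' @param problem the solved \code{AdjustmentProblem}.
#' @param result its \code{BalancingResult}.
#' @param what "gam" (adjusted GAM g'), "flux" (adjusted value of a
#'   measured reaction), or "beta" (adjusted coefficient of a component).
#' @param id reaction or component id for "flux"/"beta".
#' @param tol relative objective tolerance defining the optimal face.
#' @return numeric c(min, max).
#' @export
optimumRange <- function(problem, result, what = c("gam", "flux", "beta"),
                         id = NULL, tol = 1e-6) {
  what <- match.arg(what)
  if (result@status != "optimal") stop("result is not optimal")
  point <- switch(what,
    gam = result@gamAdjusted,
    flux = result@measurements$adjusted[match(id, result@measurements$reaction)],
    beta = result@components$adjusted[match(id, result@components$id)])
  if (problem@mode == "qp") return(c(min = point, max = point))
  v <- problem@variables
  target <- stats::setNames(numeric(nrow(v)), v$name)
  offset <- 0
  meta <- problem@meta
  if (what == "gam") {
    if (!isTRUE(meta$adjustGam)) stop("problem has no GAM slack")
    target["betaGAMp"] <- meta$gamma; target["betaGAMm"] <- -meta$gamma
    offset <- meta$g
  } else if (what == "flux") {
    if (!id %in% meta$rxns) stop(sprintf("unknown reaction '%s'", id))
    target[id] <- 1
  } else {
    k <- match(id, meta$comps$id)
    if (is.na(k)) stop(sprintf("unknown component '%s'", id))
    target[paste0("betaP_", id)] <- 1
    target[paste0("betaM_", id)] <- -1
    offset <- meta$comps$coefficient[k]
  }
  ovRow <- matrix(v$lcost, 1, dimnames = list(NULL, v$name))
  Ain <- rbind(problem@Ain, ovRow)
  bin <- c(problem@bin, result@objectiveValue * (1 + tol) + 1e-9)
  lo <- .solveCanonicalLP(target, problem@Aeq, problem@beq, Ain, bin, v$lb, v$ub)
  hi <- .solveCanonicalLP(-target, problem@Aeq, problem@beq, Ain, bin, v$lb, v$ub)
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("optimal-face subproblem failed")
  c(min = offset + lo$objval, max = offset - hi$objval)
}
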