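# Synthetic toy models: small, elementally consistent fermentation-style
# networks with a biomass reaction that satisfies the 1-g convention
# exactly, used throughout the test suite and for worked examples.
#
# Layout: glucose uptake feeds a substrate-level ATP-generating catabolic
# reaction (glc + 2 ADP + 2 Pi + 2 H+ -> 2 lactate + 2 ATP + 2 H2O, the
# stoichiometry of homolactic fermentation) and one synthesis reaction per
# biomass component. Components are drawn from a pool of real monomers
# (amino acids, a glycogen unit); their synthesis from glucose and ammonium
# is elementally balanced by construction:
#   (a/6) glc + c nh4 -> C_aH_bN_cO_d + (a-d) h2o + (4c-b+2d) h
# (negative water/proton coefficients simply mean consumption). The biomass
# reaction consumes the components in mass fractions that sum to exactly
# 1 g/gDW, plus a GAM ATP-hydrolysis block of size g.

.TOY_POOL <- data.frame(
  id = c("ala", "gly", "ser", "asp", "glu", "pro", "thr", "val", "leu",
         "glycogen"),
  formula = c("C3H7NO2", "C2H5NO2", "C3H7NO3", "C4H7NO4", "C5H9NO4",
              "C5H9NO2", "C4H9NO3", "C5H11NO2", "C6H13NO2", "C6H10O5"),
  stringsAsFactors = FALSE)

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a toy metabolic model
#'
#' Builds a feasible fermentation-style network with substrate and
#' ammonium uptake, an ATP-generating catabolic pathway, one synthesis
#' reaction per biomass component, the ATP/ADP/H2O/Pi/H+ species, and a
#' biomass reaction with an embedded GAM of \code{gam} mmol ATP/gDW. The
#' component mass fractions are sampled from the seed and the coefficients
#' solved so that the biomass weighs exactly 1 g/gDW. All metabolites carry
#' consistent chemical formulas, so the diagnostics work unmodified. The
#' same seed always yields the identical model.
#'
#' @param nComponents number of biomass components (1..10).
#' @param gam GAM value g in mmol ATP/gDW.
#' @param seed integer seed controlling composition and branch structure.
#' @param glucoseUptake maximal glucose uptake rate, mmol/(gDW h).
#' @param atpCost ATP hydrolysis cost per mmol of component synthesized
#'   (growth-independent of GAM; adds energetic realism).
#' @param defaultBound default flux bound magnitude.
#' @return a validated \code{\link{MetabolicModel-class}} whose plain FBA
#'   growth optimum is strictly positive.
#' @export
makeToyModel <- function(nComponents = 2, gam = 10, seed = 1,
                         glucoseUptake = 10, atpCost = 1,
                         defaultBound = 1000) {
  stopifnot(nComponents >= 1, nComponents <= nrow(.TOY_POOL), gam >= 0)
  sel <- .withSeed(seed, {
    idx <- sample.int(nrow(.TOY_POOL), nComponents)
    frac <- stats::runif(nComponents, 0.2, 1)
    list(idx = idx, frac = frac / sum(frac))
  })
  pool <- .TOY_POOL[sel$idx, , drop = FALSE]
  comps <- lapply(pool$formula, parseFormula)
  mw <- vapply(comps, molecularWeight, numeric(1))
  coeff <- -sel$frac / mw  # mmol/gDW, consumed: sum(-c * mw) = 1 exactly

  mets <- data.frame(
    id = c("glc", "nh4", "lac", "h2o", "h", "pi", "atp", "adp", pool$id),
    name = NA_character_,
    formula = c("C6H12O6", "H4N", "C3H6O3", "H2O", "H", "HO4P",
                "C10H12N5O13P3", "C10H12N5O10P2", pool$formula),
    compartment = "c", mw = NA_real_, stringsAsFactors = FALSE)

  hyd <- function(x) c(atp = -x, h2o = -x, adp = x, pi = x, h = x)
  addH <- function(st, extra) {
    for (nm in names(extra)) st[nm] <- sum(st[nm], extra[nm], na.rm = TRUE)
    st[st != 0]
  }
  reactions <- list(
    EX_glc = list(stoichiometry = c(glc = -1), lb = -glucoseUptake, ub = 0),
    EX_nh4 = list(stoichiometry = c(nh4 = -1), lb = -defaultBound, ub = defaultBound),
    EX_lac = list(stoichiometry = c(lac = -1), lb = 0, ub = defaultBound),
    EX_h2o = list(stoichiometry = c(h2o = -1), lb = -defaultBound, ub = defaultBound),
    EX_h = list(stoichiometry = c(h = -1), lb = -defaultBound, ub = defaultBound),
    EX_pi = list(stoichiometry = c(pi = -1), lb = -defaultBound, ub = defaultBound),
    CATABOLISM = list(
      stoichiometry = c(glc = -1, adp = -2, pi = -2, h = -2,
                        lac = 2, atp = 2, h2o = 2),
      lb = 0, ub = defaultBound))
  for (k in seq_len(nComponents)) {
    f <- comps[[k]]
    cnt <- function(e) if (e %in% names(f)) as.numeric(f[[e]]) else 0
    st <- stats::setNames(numeric(0), character(0))
    st["glc"] <- -cnt("C") / 6
    if (cnt("N") > 0) st["nh4"] <- -cnt("N")
    st[pool$id[k]] <- 1
    st["h2o"] <- sum(st["h2o"], cnt("C") - cnt("O"), na.rm = TRUE)
    st["h"] <- sum(st["h"], 4 * cnt("N") - cnt("H") + 2 * cnt("O"), na.rm = TRUE)
    if (atpCost > 0) st <- addH(st, hyd(atpCost))
    st <- st[st != 0]
    reactions[[paste0("SYN_", pool$id[k])]] <-
      list(stoichiometry = st, lb = 0, ub = defaultBound)
  }
  bioSt <- stats::setNames(coeff, pool$id)
  if (gam > 0) bioSt <- addH(bioSt, hyd(gam))
  reactions$BIOMASS <- list(stoichiometry = bioSt, lb = 0, ub = defaultBound)

  model <- metabolicModel(mets, reactions, biomassReaction = "BIOMASS")
  opt <- optimizeModel(model)
  if (opt$status != "optimal" || opt$objval <= 1e-9)
    stop("generated toy model has no positive growth optimum; adjust parameters")
  model
}

#' Perturb biomass coefficients
#'
#' Adds deltas to selected biomass component coefficients. With
#' \code{balanceComponent} set, that component's delta is solved so that
#' the perturbation is mass-neutral (sum of delta_k * MW_k = 0) and the
#' biomass still weighs 1 g; with \code{preserveMass = TRUE} and no balance
#' component, mass-neutrality of the supplied deltas is checked instead.
#' Perturbations that flip a coefficient's sign are rejected.
#'
#' @param model a \code{MetabolicModel}.
#' @param deltas named numeric, component metabolite id -> delta c
#'   (mmol/gDW).
#' @param preserveMass require mass neutrality (default TRUE).
#' @param balanceComponent optional component id whose delta is computed to
#'   make the perturbation mass-neutral.
#' @return the perturbed \code{MetabolicModel}.
#' @export
perturbBiomass <- function(model, deltas, preserveMass = TRUE,
                           balanceComponent = NULL) {
  br <- model@biomassReaction
  if (is.na(br)) stop("model has no biomass reaction")
  st <- model@stoichiometry[, br]
  st <- st[st != 0]
  unknown <- setdiff(c(names(deltas), balanceComponent), names(st))
  if (length(unknown))
    stop(sprintf("not a biomass component: %s", paste(unknown, collapse = ", ")))
  mwOf <- function(id) {
    w <- .metaboliteMw(model, id)
    if (is.na(w)) stop(sprintf("no molecular weight for component '%s'", id))
    w
  }
  if (!is.null(balanceComponent)) {
    mwB <- mwOf(balanceComponent)
    massShift <- sum(vapply(names(deltas), mwOf, numeric(1)) * as.numeric(deltas))
    deltas[balanceComponent] <- -massShift / mwB
  } else if (preserveMass) {
    massShift <- sum(vapply(names(deltas), mwOf, numeric(1)) * as.numeric(deltas))
    if (abs(massShift) > 1e-9)
      stop(sprintf("perturbation changes the biomass weight by %.3g g; pass mass-neutral deltas or set balanceComponent", massShift))
  }
  newSt <- st
  for (id in names(deltas)) {
    newSt[id] <- st[id] + deltas[[id]]
    if (sign(newSt[id]) != sign(st[id]) && abs(deltas[[id]]) > 0)
      stop(sprintf("perturbation flips the sign of component '%s'", id))
  }
  .setReactionStoichiometry(model, br, newSt[newSt != 0])
}

#' Simulate a measurement set from a model
#'
#' Solves an FBA, extracts the exchange fluxes and the growth rate, and
#' optionally adds independent zero-mean Gaussian noise with the given
#' standard deviations. The sds are recorded in the measurement set; a
#' fixed seed reproduces the values exactly.
#'
#' @param model a feasible \code{MetabolicModel}.
#' @param sdProfile named numeric of absolute standard deviations per
#'   reaction id; reactions not listed get sd \code{NA} and no noise.
#' @param noiseSeed integer seed for the Gaussian noise.
#' @param include optional character vector restricting which reactions are
#'   reported (default: all exchanges plus the biomass reaction).
#' @return a \code{\link{MeasurementSet-class}}.
#' @export
simulateMeasurements <- function(model, sdProfile = numeric(),
                                 noiseSeed = 1, include = NULL) {
  opt <- optimizeModel(model)
  if (opt$status != "optimal") stop("model FBA is not optimal; cannot simulate")
  if (is.null(include)) {
    include <- reactionIds(model)[.isExchange(model)]
    if (!is.na(model@biomassReaction))
      include <- c(include, model@biomassReaction)
  }
  vals <- opt$fluxes[include]
  sds <- stats::setNames(rep(NA_real_, length(include)), include)
  sds[names(sdProfile)[names(sdProfile) %in% include]] <-
    sdProfile[names(sdProfile) %in% include]
  noisy <- sds[!is.na(sds)]
  if (length(noisy)) {
    noise <- .withSeed(noiseSeed, stats::rnorm(length(noisy), 0, as.numeric(noisy)))
    vals[names(noisy)] <- vals[names(noisy)] + noise
  }
  measurementSet(include, as.numeric(vals), as.numeric(sds))
}
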