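# Shared fixtures: tiny hand-built models and random toy scenarios.

# Linear chain: nutrient in, convert, product out. All formulas CH2O-ish so
# elemental checks stay trivial.
chainModel <- function(ubIn = 10) {
  metabolicModel(
    data.frame(id = c("A", "B"), formula = c("C6H12O6", "C6H12O6")),
    list(
      EX_A = list(stoichiometry = c(A = 1), lb = 0, ub = ubIn),
      CONV = list(stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000),
      EX_B = list(stoichiometry = c(B = -1), lb = 0, ub = 1000)),
    biomassReaction = "EX_B")
}

# Toy model with a mass-neutral two-component biomass perturbation applied;
# returns everything a recovery test needs.
perturbedToy <- function(seed, relDelta = 0.1, nComponents = 3, gam = 10) {
  model <- makeToyModel(nComponents = nComponents, gam = gam, seed = seed)
  opt <- optimizeModel(model)
  spec <- extractBiomassSpec(model)$spec
  comp <- spec@components
  d1 <- relDelta * abs(comp$coefficient[1])
  perturbed <- perturbBiomass(model, stats::setNames(d1, comp$id[1]),
                              balanceComponent = comp$id[2])
  d2 <- -d1 * comp$mw[1] / comp$mw[2]
  list(model = model, perturbed = perturbed, fluxes = opt$fluxes,
       deltas = stats::setNames(c(d1, d2), comp$id[1:2]), components = comp)
}

# Small random branched network (<= 5 reactions) with a consistent flux
# vector, for solver oracle tests: EX_in -> M1, two branches to M2, out.
randomTinyProblem <- function(seed, mode = "qp") {
  set.seed(seed)
  mets <- data.frame(id = c("M1", "M2"))
  rx <- list(
    EX_in = list(stoichiometry = c(M1 = 1), lb = 0, ub = 10),
    R1 = list(stoichiometry = c(M1 = -1, M2 = 1), lb = 0, ub = 6),
    R2 = list(stoichiometry = c(M1 = -1, M2 = 1), lb = 0, ub = 6),
    EX_out = list(stoichiometry = c(M2 = -1), lb = 0, ub = 12))
  model <- metabolicModel(mets, rx, biomassReaction = "EX_out")
  # inconsistent measurements around a feasible point
  x0 <- runif(1, 1, 8)
  noise <- round(runif(3, -2, 2), 2)
  meas <- measurementSet(c("EX_in", "EX_out", "R1"),
                         c(x0 + noise[1], x0 + noise[2],
                           min(x0 / 2 + noise[3], 6)),
                         sd = c(0.5, 0.25, 1))
  cfg <- adjustmentConfig(mode = mode)
  list(model = model, measurements = meas, config = cfg)
}
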