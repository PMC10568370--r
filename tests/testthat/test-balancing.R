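test_that("flux weight schemes follow the measurement table conventions", {
  meas <- measurementSet(c("g", "l", "x"), c(0.46, 0, 13.48),
                         sd = c(0.02, 0, NA))
  w <- suppressWarnings(
    defaultFluxWeights(meas, "sd_reciprocal", fluxScale = 1))
  expect_equal(w$weight[w$reaction == "g"], 50)       # 1/0.02
  expect_true(w$hard[w$reaction == "l"])              # sd 0 -> exact
  # missing sd falls back to relative weighting, with a warning
  expect_warning(defaultFluxWeights(meas, "sd_reciprocal"), "no sd")
  expect_equal(w$weight[w$reaction == "x"], 1 / 13.48, tolerance = 1e-12)
  # relative scheme with a scale: the Table-3-style 100x priority factor
  wr <- defaultFluxWeights(measurementSet("x", 13.48, sd = NA),
                           "relative", fluxScale = 0.01)
  expect_equal(wr$weight, 100 / 13.48, tolerance = 1e-12)
  # squared reciprocal variant
  ws <- defaultFluxWeights(measurementSet("g", 0.46, sd = 0.02),
                           "sd_reciprocal", sdSquared = TRUE)
  expect_equal(ws$weight, 2500)
  expect_error(defaultFluxWeights(meas, "custom"), "no custom weight")
})

test_that("biomass/GAM adjustment demands a fixed growth rate", {
  model <- makeToyModel(3, 10, 1)
  meas <- simulateMeasurements(model, sdProfile = c(EX_glc = 0.1, EX_lac = 0.1),
                               include = c("EX_glc", "EX_lac"))
  cfg <- adjustmentConfig(adjustGam = TRUE)
  expect_error(balanceFluxes(model, meas, config = cfg), "bilinear")
})

test_that("perturbation recovery returns beta = -Delta pointwise", {
  tc <- perturbedToy(seed = 5, relDelta = 0.12)
  r <- recoverBiomassPerturbation(tc$perturbed, tc$fluxes)
  expect_equal(solverStatus(r), "optimal")
  comp <- componentAdjustments(r)
  got <- stats::setNames(comp$beta, comp$id)
  expect_equal(got[names(tc$deltas)], -tc$deltas, tolerance = 1e-8)
  other <- setdiff(comp$id, names(tc$deltas))
  expect_true(all(abs(got[other]) < 1e-8))
  # the recovered coefficients are the unperturbed ones
  orig <- extractBiomassSpec(tc$model)$spec@components
  expect_equal(comp$adjusted[match(orig$id, comp$id)], orig$coefficient,
               tolerance = 1e-8)
  # zero perturbation -> zero corrections
  r0 <- recoverBiomassPerturbation(tc$model, tc$fluxes)
  expect_equal(objectiveValue(r0), 0, tolerance = 1e-10)
  expect_true(all(abs(componentAdjustments(r0)$beta) < 1e-8))
})

test_that("GAM-only adjustment recovers a scaled GAM exactly", {
  for (phi in c(0.6, 0.85, 1)) {
    g <- 10
    mTrue <- makeToyModel(3, gam = phi * g, seed = 12)
    model <- makeToyModel(3, gam = g, seed = 12)
    meas <- simulateMeasurements(mTrue, include = c("EX_glc", "EX_lac", "BIOMASS"))
    for (mode in c("qp", "lp")) {
      cfg <- adjustmentConfig(mode = mode, adjustFluxes = FALSE, adjustGam = TRUE)
      r <- balanceFluxes(model, meas, config = cfg)
      expect_equal(solverStatus(r), "optimal")
      expect_equal(adjustedGam(r), phi * g, tolerance = 1e-6 * phi * g)
      # reported g' honors the sign convention g' = g + gamma * betaGAM
      expect_equal(r@gamInitial + r@gamma * r@betaGam, adjustedGam(r))
    }
  }
})

test_that("applyResult writes adjustments into the biomass reaction", {
  g <- 10
  mTrue <- makeToyModel(3, gam = 0.7 * g, seed = 21)
  model <- makeToyModel(3, gam = g, seed = 21)
  meas <- simulateMeasurements(mTrue, include = c("EX_glc", "EX_lac", "BIOMASS"))
  cfg <- adjustmentConfig(adjustFluxes = FALSE, adjustGam = TRUE)
  r <- balanceFluxes(model, meas, config = cfg)
  adjusted <- applyResult(model, r)
  ex2 <- extractBiomassSpec(adjusted)
  expect_equal(ex2$gam@g, adjustedGam(r), tolerance = 1e-9)
  # ADP coefficient moved to g' in the stoichiometry itself
  adp <- ex2$gam@roles$id[ex2$gam@roles$role == "adp"]
  expect_equal(unname(stoichiometry(adjusted)[adp, biomassReaction(adjusted)]),
               adjustedGam(r), tolerance = 1e-9)
  # all-zero result leaves the model unchanged
  measOK <- simulateMeasurements(model, include = c("EX_glc", "EX_lac", "BIOMASS"))
  r0 <- balanceFluxes(model, measOK, config = cfg)
  same <- applyResult(model, r0)
  expect_equal(as.matrix(stoichiometry(same)), as.matrix(stoichiometry(model)),
               tolerance = 1e-9)
  expect_error(applyResult(model, methods::new("BalancingResult",
    status = "infeasible", objectiveValue = NA_real_,
    fluxes = numeric(0), measurements = data.frame(),
    components = data.frame(), betaGam = NA_real_, gamInitial = NA_real_,
    gamAdjusted = NA_real_, gamma = 0, mode = "qp", diagnostics = list())),
    "non-optimal")
})

test_that("optima satisfy mass conservation and the adjustment bounds", {
  for (seed in 1:6) {
    tc <- perturbedToy(seed, relDelta = 0.08)
    r <- recoverBiomassPerturbation(tc$perturbed, tc$fluxes)
    expect_equal(solverStatus(r), "optimal")
    comp <- componentAdjustments(r)
    scale <- max(1, max(abs(comp$beta)))
    expect_lt(abs(sum(comp$beta * comp$mw)) / scale, 1e-8)
    expect_true(all(abs(comp$beta) <= 0.3 * abs(comp$coefficient) + 1e-9))
  }
})

test_that("the optimal-face post-pass brackets the reported quantity", {
  g <- 12
  mTrue <- makeToyModel(3, gam = 7, seed = 31)
  model <- makeToyModel(3, gam = g, seed = 31)
  meas <- simulateMeasurements(mTrue, include = c("EX_glc", "EX_lac", "BIOMASS"))
  cfg <- adjustmentConfig(mode = "lp", adjustFluxes = FALSE, adjustGam = TRUE)
  p <- buildAdjustmentProblem(model, meas, config = cfg)
  r <- solveAdjustmentProblem(p)
  rng <- optimumRange(p, r, "gam")
  expect_lte(rng[["min"]], adjustedGam(r) + 1e-6)
  expect_gte(rng[["max"]], adjustedGam(r) - 1e-6)
  # QP results are unique: the range collapses to the point
  cfgQ <- adjustmentConfig(mode = "qp", adjustFluxes = FALSE, adjustGam = TRUE)
  pq <- buildAdjustmentProblem(model, meas, config = cfgQ)
  rq <- solveAdjustmentProblem(pq)
  expect_equal(unname(optimumRange(pq, rq, "gam")),
               rep(adjustedGam(rq), 2))
})
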