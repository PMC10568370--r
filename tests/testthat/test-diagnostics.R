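test_that("biomass elemental content is the signed sum over components", {
  # hand-built biomass: consumes 10 glucose-monomer units (C6H10O5) and
  # produces 1 water per gDW
  mets <- data.frame(id = c("unit", "h2o"), formula = c("C6H10O5", "H2O"))
  rx <- list(
    SRC = list(stoichiometry = c(unit = 1), lb = 0, ub = 100),
    WOUT = list(stoichiometry = c(h2o = -1), lb = -100, ub = 100),
    BIO = list(stoichiometry = c(unit = -10, h2o = 1), lb = 0, ub = 10))
  model <- metabolicModel(mets, rx, biomassReaction = "BIO")
  spec <- methods::new("BiomassSpec",
    components = data.frame(id = c("unit", "h2o"), coefficient = c(-10, 1),
                            mw = c(0.162141, 0.018015)),
    biomassReaction = "BIO")
  content <- biomassElementalContent(model, spec)
  expect_equal(content[["C"]], 60)
  expect_equal(content[["O"]], 50 - 1)  # produced water gives elements back
  expect_equal(content[["H"]], 100 - 2)
  # a missing formula is reported by metabolite name
  model2 <- model
  model2@metabolites$formula[1] <- NA
  expect_error(biomassElementalContent(model2, spec), "unit")
})

test_that("elemental balance is zero for consistent fluxes and linear in rates", {
  model <- makeToyModel(nComponents = 3, gam = 10, seed = 8)
  meas <- simulateMeasurements(model)
  spec <- extractBiomassSpec(model)$spec
  eb <- elementalBalance(model, meas, spec)
  expect_true(all(abs(eb@net) < 1e-7))
  # contributions sum to the net
  expect_equal(unname(rowSums(eb@contributions)), unname(eb@net))
  # doubling all rates doubles every element's net
  d <- measurements(meas)
  meas3 <- measurementSet(d$reaction, d$value * 2, d$sd)
  # drop one output so the net is nonzero and scaling is visible
  d2 <- d[d$reaction != "EX_lac", ]
  m1 <- measurementSet(d2$reaction, d2$value, d2$sd)
  m2 <- measurementSet(d2$reaction, 2 * d2$value, d2$sd)
  n1 <- elementalBalance(model, m1, spec)@net
  n2 <- elementalBalance(model, m2, spec)@net
  expect_gt(max(abs(n1)), 1e-3)
  expect_equal(n2, 2 * n1, tolerance = 1e-9)
})

test_that("a known carbon surplus in the measurements is quantified", {
  model <- makeToyModel(nComponents = 3, gam = 10, seed = 8)
  meas <- simulateMeasurements(model)
  spec <- extractBiomassSpec(model)$spec
  d <- measurements(meas)
  # feed one extra mmol/(gDW h) of glucose on top of a consistent set:
  # surplus of exactly 6 carbon, 12 hydrogen, 6 oxygen
  d$value[d$reaction == "EX_glc"] <- d$value[d$reaction == "EX_glc"] - 1
  net <- elementalBalance(model, measurementSet(d$reaction, d$value, d$sd),
                          spec)@net
  expect_equal(net[["C"]], 6, tolerance = 1e-7)
  expect_equal(net[["H"]], 12, tolerance = 1e-7)
  expect_equal(net[["O"]], 6, tolerance = 1e-7)
  # a measured internal reaction is excluded with a warning
  dd <- rbind(d, data.frame(reaction = "CATABOLISM", value = 1, sd = NA))
  expect_warning(
    elementalBalance(model, measurementSet(dd$reaction, dd$value, dd$sd), spec),
    "neither an exchange")
})

test_that("FVA ranges match enumerable bounds and flag out-of-range values", {
  model <- chainModel(ubIn = 10)
  # chain forces all three rates equal; feasible range is [0, 10]
  meas <- measurementSet(c("EX_A", "CONV", "EX_B"), c(12, 5, 10))
  fva <- fvaPrecheck(model, meas)
  expect_equal(fva$min, rep(0, 3))
  expect_equal(fva$max, rep(10, 3))
  expect_equal(fva$inRange, c(FALSE, TRUE, TRUE))  # boundary value counts
  # unbounded direction reported as infinity
  m2 <- metabolicModel(data.frame(id = "A"),
    list(IN = list(stoichiometry = c(A = 1), lb = 0, ub = 5),
         OUT1 = list(stoichiometry = c(A = -1), lb = -Inf, ub = Inf),
         OUT2 = list(stoichiometry = c(A = -1), lb = -Inf, ub = Inf)))
  f2 <- fvaPrecheck(m2, measurementSet("OUT1", 3))
  expect_equal(f2$min, -Inf)
  expect_equal(f2$max, Inf)
  # the balancing solution always lies inside the FVA range
  tc <- randomTinyProblem(3, "qp")
  fva3 <- fvaPrecheck(tc$model, tc$measurements)
  res <- balanceFluxes(tc$model, tc$measurements, config = tc$config)
  r <- fluxes(res)[fva3$reaction]
  expect_true(all(r >= fva3$min - 1e-7 & r <= fva3$max + 1e-7))
})

test_that("constrained maximum growth reduces to FBA and respects fixes", {
  model <- makeToyModel(nComponents = 2, gam = 6, seed = 13)
  plain <- maxGrowth(model)
  expect_equal(plain$status, "optimal")
  expect_equal(plain$growth, optimizeModel(model)$objval, tolerance = 1e-9)
  # no substrate, no growth
  g0 <- maxGrowth(model, measurementSet("EX_glc", 0))
  expect_equal(g0$growth, 0, tolerance = 1e-9)
  # halving the substrate halves the achievable growth (linear toy)
  full <- maxGrowth(model, measurementSet("EX_glc", -10))
  half <- maxGrowth(model, measurementSet("EX_glc", -5))
  expect_equal(half$growth, full$growth / 2, tolerance = 1e-6)
  # excluded ids are dropped before fixing
  gx <- maxGrowth(model, measurementSet(c("EX_glc", "EX_lac"), c(-5, 1e6)),
                  exclude = "EX_lac")
  expect_equal(gx$growth, half$growth, tolerance = 1e-9)
})

test_that("component maintenance estimates sum to a GAM lower bound", {
  expect_equal(gamLowerBound(c(dna = 21.970, rna = 0.256, protein = 0.137)),
               22.363)
  expect_equal(gamLowerBound(numeric()), 0)
  expect_equal(gamLowerBound(c(a = 5)), 5)
  expect_error(gamLowerBound(c(a = -1)), "non-negative")
})
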