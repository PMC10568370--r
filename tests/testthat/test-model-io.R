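test_that("model construction enforces the structural invariants", {
  mets <- data.frame(id = c("A", "B"))
  expect_error(
    metabolicModel(mets, list(R1 = list(stoichiometry = c(Z = 1)))),
    "unknown metabolite")
  expect_error(
    metabolicModel(mets, list(R1 = list(stoichiometry = c(A = 1), lb = 2, ub = 1))),
    "lower bound exceeds")
  expect_error(
    metabolicModel(mets, list(R1 = list(stoichiometry = c(A = 1))),
                   biomassReaction = "NOPE"),
    "not in the model")
  m <- chainModel()
  expect_equal(nReactions(m), 3L)
  expect_equal(nMetabolites(m), 2L)
  expect_equal(biomassReaction(m), "EX_B")
})

test_that("measurement sets validate values and model compatibility", {
  expect_error(measurementSet("R1", 1, sd = -0.1), "non-negative")
  expect_error(measurementSet(c("R1", "R1"), c(1, 2)), "duplicated")
  m <- chainModel()
  expect_error(
    .checkMeasurementsAgainstModel(m, measurementSet("NOPE", 1)),
    "not in the model")
  # reactions already fixed by lb == ub cannot be measured on top
  mf <- metabolicModel(data.frame(id = "A"),
                       list(R1 = list(stoichiometry = c(A = 1), lb = 2, ub = 2),
                            R2 = list(stoichiometry = c(A = -1), lb = 0, ub = 5)))
  expect_error(
    .checkMeasurementsAgainstModel(mf, measurementSet("R1", 2)),
    "fixed model bounds")
})

test_that("SBML round-trip preserves the model element-wise", {
  model <- makeToyModel(nComponents = 3, gam = 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(model, path)
  back <- readSBMLModel(path)
  expect_setequal(reactionIds(back), reactionIds(model))
  expect_setequal(metaboliteIds(back), metaboliteIds(model))
  S1 <- as.matrix(stoichiometry(model))
  S2 <- as.matrix(stoichiometry(back))[rownames(S1), colnames(S1)]
  expect_equal(S2, S1, tolerance = 1e-12)
  expect_equal(lowerBounds(back)[reactionIds(model)], lowerBounds(model))
  expect_equal(upperBounds(back)[reactionIds(model)], upperBounds(model))
  expect_equal(biomassReaction(back), biomassReaction(model))
  fm <- model@metabolites$formula[order(model@metabolites$id)]
  fb <- back@metabolites$formula[order(back@metabolites$id)]
  expect_equal(fb, fm)
})

test_that("explicit molecular weights survive SBML round-trip via notes", {
  model <- makeToyModel(nComponents = 4, gam = 10, seed = 7)
  spec <- extractBiomassSpec(model)$spec
  cm <- stats::setNames(rep(c("protein", "carb"), length.out = nrow(spec@components)),
                        spec@components$id)
  lumped <- lumpBiomass(model, cm)
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(lumped, path)
  back <- readSBMLModel(path)
  o1 <- order(lumped@metabolites$id); o2 <- order(back@metabolites$id)
  expect_equal(back@metabolites$mw[o2], lumped@metabolites$mw[o1],
               tolerance = 1e-12)
})

test_that("SBML reader rejects malformed models with descriptive errors", {
  path <- withr::local_tempfile(fileext = ".xml")
  model <- chainModel()
  writeSBMLModel(model, path)
  # strip the objective -> biomass undetectable without an override
  txt <- readLines(path)
  writeLines(txt[!grepl("Objective", txt)], path)
  expect_error(readSBMLModel(path), "no biomass reaction")
  expect_equal(biomassReaction(readSBMLModel(path, biomassReaction = "EX_B")),
               "EX_B")
  # strip a bound attribute
  writeSBMLModel(model, path)
  txt <- readLines(path)
  txt <- sub(' fbc:lowerFluxBound="bnd_lb_1"', "", txt)
  writeLines(txt, path)
  expect_error(readSBMLModel(path), "lacks FBC flux bounds")
  expect_error(readSBMLModel(withr::local_tempfile(fileext = ".xml")))
})

test_that("scenario files round-trip through YAML and JSON", {
  model <- makeToyModel(3, 10, 42)
  meas <- simulateMeasurements(model,
                               sdProfile = c(EX_glc = 0.2, BIOMASS = 0.01),
                               include = c("EX_glc", "EX_lac", "BIOMASS"))
  cfg <- adjustmentConfig(mode = "lp", adjustGam = TRUE, gamMaxChange = 5,
                          fluxScale = 0.01, fluxWeightScheme = "relative")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    writeScenario(meas, cfg, path, gamOverrides = c(atp = "atp"))
    sc <- readScenario(path, model)
    expect_equal(measurements(sc$measurements)$value,
                 measurements(meas)$value, tolerance = 1e-10)
    expect_equal(measurements(sc$measurements)$sd, measurements(meas)$sd,
                 tolerance = 1e-10)
    expect_equal(sc$config@mode, "lp")
    expect_equal(sc$config@gamMaxChange, 5)
    expect_equal(sc$config@fluxScale, 0.01)
    expect_true(sc$config@adjustGam)
    expect_equal(unname(sc$gamOverrides[["atp"]]), "atp")
  }
})

test_that("scenario validation catches schema violations", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("measurements: {}\n", path)
  expect_error(readScenario(path), "no measurements")
  writeLines(c("measurements:", "  R1: {value: 1}", "bogus_key: 2"), path)
  expect_error(readScenario(path), "unknown scenario key")
  writeLines(c("measurements:", "  R1: {value: 1, sd: -1}"), path)
  expect_error(readScenario(path), "non-negative")
  # omitted sd becomes NA
  writeLines(c("measurements:", "  EX_A: {value: 1}"), path)
  sc <- readScenario(path)
  expect_true(is.na(measurements(sc$measurements)$sd))
})
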