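# The staged guideline and its comparison report, exercised on a scenario
# whose ground truth is known: measurements generated from a twin toy model
# with a smaller GAM, so the model GAM is overestimated for the "data".

guidelineFixture <- function() {
  mTrue <- makeToyModel(3, gam = 6, seed = 11)
  model <- makeToyModel(3, gam = 12, seed = 11)
  meas <- simulateMeasurements(mTrue,
    sdProfile = c(EX_glc = 0.05, EX_lac = 0.1, BIOMASS = 0.005),
    noiseSeed = 2, include = c("EX_glc", "EX_lac", "BIOMASS"))
  list(model = model, meas = meas, trueGam = 6)
}

test_that("the guideline runs all steps and flags the infeasible ones", {
  fx <- guidelineFixture()
  gl <- runGuideline(fx$model, fx$meas)
  expect_false(gl@step0$feasible)
  expect_s4_class(gl@step0$elemental, "ElementalBalanceReport")
  expect_true(all(c("step1_lp", "step1_qp", "step2a", "step2b", "step2c",
                    "step3") %in% names(gl@scenarios)))
  s <- gl@scenarios
  expect_equal(s$step1_lp$result@status, "optimal")
  expect_equal(s$step1_qp$result@status, "optimal")
  expect_equal(s$step3$result@status, "optimal")
  # flux-only corrections must lower the growth rate below the measurement
  # (the model cannot sustain it with its inflated GAM)
  mu <- measurements(fx$meas)$value[3]
  expect_lt(s$step1_qp$result@measurements$adjusted[3], mu)
  # GAM-only adjustment keeps growth fixed and reduces GAM toward truth
  if (s$step2a$result@status == "optimal")
    expect_lt(adjustedGam(s$step2a$result), 12)
  # the merged step recovers a GAM near the generating value
  expect_equal(adjustedGam(s$step3$result), fx$trueGam, tolerance = 0.25)
})

test_that("step-3 never exceeds step-1 under the shared merged objective", {
  fx <- guidelineFixture()
  gl <- runGuideline(fx$model, fx$meas)
  ov1 <- gl@scenarios$step1_qp$result@objectiveValue
  ov3 <- gl@scenarios$step3$result@objectiveValue
  expect_lte(ov3, ov1 + 1e-9)
})

test_that("feasible measurements give OV 0 in every scenario", {
  model <- makeToyModel(3, gam = 10, seed = 23)
  meas <- simulateMeasurements(model, include = c("EX_glc", "EX_lac", "BIOMASS"))
  cfg <- adjustmentConfig(fluxWeightScheme = "relative")
  gl <- runGuideline(model, meas, cfg)
  expect_true(gl@step0$feasible)
  for (nm in names(gl@scenarios)) {
    res <- gl@scenarios[[nm]]$result
    expect_equal(res@status, "optimal", info = nm)
    expect_equal(res@objectiveValue, 0, tolerance = 1e-8, info = nm)
  }
})

test_that("the comparison table lists every measured rate exactly once", {
  fx <- guidelineFixture()
  gl <- runGuideline(fx$model, fx$meas)
  tab <- renderComparison(gl, "data.frame")
  ids <- measurements(fx$meas)$reaction
  for (id in ids) expect_equal(sum(tab$quantity == id), 1L)
  expect_true("OV" %in% tab$quantity)
  expect_true("GAM" %in% tab$quantity)
  # hard-fixed growth prints as Fixed in biomass-adjusting scenarios
  expect_equal(tab$step3[tab$quantity == "BIOMASS"], "Fixed")
  # tsv/markdown/json renderings carry the same grid
  tsv <- renderComparison(gl, "tsv")
  expect_equal(length(strsplit(tsv, "\n")[[1]]), nrow(tab) + 1L)
  md <- renderComparison(gl, "markdown")
  expect_match(md, "\\| quantity \\|")
  js <- jsonlite::fromJSON(renderComparison(gl, "json"))
  expect_equal(nrow(js), nrow(tab))
  expect_equal(js$quantity, tab$quantity)
})

test_that("unchanged corrections print as Unchanged", {
  model <- makeToyModel(3, gam = 10, seed = 23)
  meas <- simulateMeasurements(model, include = c("EX_glc", "EX_lac", "BIOMASS"))
  gl <- runGuideline(model, meas, adjustmentConfig(fluxWeightScheme = "relative"))
  tab <- renderComparison(gl, "data.frame")
  col <- tab$step1_qp[tab$quantity %in% measurements(meas)$reaction]
  expect_true(all(col %in% c("Unchanged", "Fixed")))
})

test_that("NGAM-like demands are reported in the step-0 checklist", {
  model <- makeToyModel(3, gam = 10, seed = 29)
  # add an ATP hydrolysis reaction with a positive lower bound (NGAM)
  ngam <- c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)
  model2 <- .addReaction(model, "NGAM", ngam, lb = 1, ub = 1000)
  meas <- simulateMeasurements(model2, include = c("EX_glc", "EX_lac", "BIOMASS"))
  gl <- runGuideline(model2, meas, adjustmentConfig(fluxWeightScheme = "relative"))
  expect_match(paste(gl@step0$ngamWarnings, collapse = " "), "NGAM")
})
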