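test_that("GAM is detected from the ADP coefficient and split off", {
  model <- makeToyModel(nComponents = 3, gam = 10, seed = 1)
  ex <- extractBiomassSpec(model)
  expect_equal(ex$gam@g, 10)
  expect_setequal(ex$gam@roles$role, c("atp", "adp", "h2o", "pi", "h"))
  # ATP/H2O consumed, ADP/Pi/H produced
  signs <- stats::setNames(ex$gam@roles$sign, ex$gam@roles$role)
  expect_equal(signs[["atp"]], -1)
  expect_equal(signs[["h2o"]], -1)
  expect_equal(signs[["adp"]], 1)
  # pure GAM carriers (cB = 0) are not adjustable components
  expect_false(any(ex$gam@roles$id %in% ex$spec@components$id))
  # |cGAM| = g for every role metabolite
  cg <- ex$gam@split$cGAM[match(ex$gam@roles$id, ex$gam@split$id)]
  expect_equal(abs(cg), rep(10, 5))
})

test_that("biomass mass check implements the 1-g convention", {
  model <- makeToyModel(nComponents = 4, gam = 12, seed = 3)
  ex <- extractBiomassSpec(model)
  expect_equal(checkBiomassMass(ex$spec), 1, tolerance = 1e-12)
  # doubling one coefficient adds |c| * MW grams
  comp <- ex$spec@components
  spec2 <- ex$spec
  spec2@components$coefficient[1] <- 2 * comp$coefficient[1]
  expect_warning(got <- checkBiomassMass(spec2), "deviates")
  expect_equal(got, 1 + abs(comp$coefficient[1]) * comp$mw[1],
               tolerance = 1e-10)
  # a GAM-only pseudo-biomass weighs nothing: hydrolysis is mass-balanced
  mets <- model@metabolites
  rx <- list(GAMONLY = list(
    stoichiometry = c(atp = -5, h2o = -5, adp = 5, pi = 5, h = 5),
    lb = 0, ub = 10))
  gm <- metabolicModel(mets, rx, biomassReaction = "GAMONLY")
  exg <- extractBiomassSpec(gm)
  expect_equal(exg$gam@g, 5)
  expect_equal(nrow(exg$spec@components), 0L)
  expect_equal(-sum(exg$spec@components$coefficient * exg$spec@components$mw), 0)
})

test_that("GAM extraction into a separate reaction is exact and idempotent-guarded", {
  model <- makeToyModel(nComponents = 2, gam = 10, seed = 2)
  ex <- extractBiomassSpec(model)
  out <- gamToSeparateReaction(model, ex$gam)
  st <- stoichiometry(out$model)[, out$reactionId]
  expect_equal(unname(st["atp"]), -10)
  expect_equal(unname(st["h2o"]), -10)
  expect_equal(unname(st["adp"]), 10)
  expect_equal(unname(st["pi"]), 10)
  expect_equal(unname(st["h"]), 10)
  # the added reaction is elementally balanced
  counts <- lapply(rownames(stoichiometry(out$model)), function(id) {
    f <- out$model@metabolites$formula[match(id, out$model@metabolites$id)]
    if (is.na(f)) return(NULL)
    parseFormula(f)
  })
  net <- stats::setNames(numeric(0), character(0))
  sv <- stoichiometry(out$model)[, out$reactionId]
  for (i in seq_along(sv)) {
    if (sv[i] == 0 || is.null(counts[[i]])) next
    for (e in names(counts[[i]]))
      net[e] <- sum(net[e], sv[i] * counts[[i]][[e]], na.rm = TRUE)
  }
  expect_true(all(abs(net) < 1e-9))
  # re-extraction on the modified model finds no GAM; applying twice errors
  ex2 <- extractBiomassSpec(out$model)
  expect_equal(ex2$gam@g, 0)
  expect_error(gamToSeparateReaction(out$model, ex2$gam), "already extracted")
  # mass check is invariant under GAM extraction
  expect_equal(checkBiomassMass(ex2$spec), checkBiomassMass(ex$spec),
               tolerance = 1e-12)
})

test_that("lumping collects components into pseudo-metabolites and preserves mass and growth", {
  model <- makeToyModel(nComponents = 4, gam = 31.578, seed = 9)
  ex <- extractBiomassSpec(model)
  comp <- ex$spec@components
  cm <- stats::setNames(c("protein", "protein", "rna", "rna"), comp$id)
  # per-class maintenance: the published polymerization estimates for
  # protein/DNA/RNA sum to 22.363 mmol/gDW, leaving 9.215 in the biomass
  maint <- c(protein = 21.970, rna = 0.256 + 0.137)
  expect_equal(gamLowerBound(maint), 22.363)
  lumped <- lumpBiomass(model, cm, maint)
  exL <- extractBiomassSpec(lumped)
  expect_equal(exL$gam@g, 31.578 - 22.363, tolerance = 1e-9)
  # exactly the two pseudo-metabolites remain as organic reactants
  expect_setequal(exL$spec@components$id, c("pseudo_protein", "pseudo_rna"))
  expect_equal(exL$spec@components$coefficient, c(-1, -1))
  # total mass unchanged
  expect_equal(checkBiomassMass(exL$spec), checkBiomassMass(ex$spec),
               tolerance = 1e-9)
  # producible biomass unchanged
  expect_equal(optimizeModel(lumped)$objval, optimizeModel(model)$objval,
               tolerance = 1e-7)
})

test_that("lumping validates class coverage and maintenance budget", {
  model <- makeToyModel(nComponents = 3, gam = 5, seed = 4)
  comp <- extractBiomassSpec(model)$spec@components
  cmPartial <- stats::setNames("protein", comp$id[1])
  expect_error(lumpBiomass(model, cmPartial), "not assigned to a class")
  cmAll <- stats::setNames(rep("protein", nrow(comp)), comp$id)
  expect_error(lumpBiomass(model, cmAll, c(protein = 6)), "exceeds")
})
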