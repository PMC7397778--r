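test_that("case-level splits are disjoint, exhaustive and swap across folds", {
  ids <- sprintf("C%02d", 1:10)
  spec <- splitSpec(seed = 4)
  folds <- splitCases(ids, spec)
  f1 <- folds[[1]]
  expect_length(f1$train, 4)
  expect_length(f1$validation, 1)
  expect_length(f1$test, 5)
  expect_setequal(c(f1$train, f1$validation, f1$test), ids)
  expect_equal(length(intersect(f1$train, f1$test)), 0)
  expect_equal(length(intersect(f1$validation, f1$test)), 0)
  f2 <- folds[[2]]
  expect_setequal(f2$test, c(f1$train, f1$validation))
  expect_setequal(c(f2$train, f2$validation), f1$test)
  expect_identical(folds, splitCases(ids, spec))
  expect_error(splitCases(ids[1:4], spec), "at least 5")
})

microOpts <- function() {
  regimeOptions(
    genSpec = generatorSpec(blocks = 1, baseWidth = 4),
    discSpec = discriminatorSpec(baseWidth = 8, kernels = c(4, 4, 4),
                                 strides = c(2, 2, 1)),
    ganConfig = ganTrainConfig(iterations = 3),
    regSpec = regressorSpec(2, 2, 4),
    regTrainConfig = regTrainConfig(epochs = 1),
    evalCfg = evalConfig(radius = 8, etaGrid = c(0, 0.5, 1)))
}

test_that("mixed regime with k = 0 reduces to the adapted regime", {
  lp <- layoutParams()
  dd <- makeDomainDatasets(lp, styleParams(), targetStyleParams(), 6, 6, 77)
  opts <- microOpts()
  a <- runRegime(dd$source, dd$target, regimeSpec("adapted"), opts, 5)
  m <- runRegime(dd$source, dd$target, regimeSpec("mixed", k = 0), opts, 5)
  expect_identical(detectionMetrics(a), detectionMetrics(m))
  expect_identical(classMetrics(a), classMetrics(m))
  expect_error(runRegime(dd$source, dd$target,
                         regimeSpec("mixed", k = 100), opts, 5),
               "exceeds")
})

test_that("the audit log proves target test labels stay untouched", {
  lp <- layoutParams()
  dd <- makeDomainDatasets(lp, styleParams(), targetStyleParams(), 6, 6, 78)
  opts <- microOpts()
  for (r in c("baseline_source_only", "mixed", "target_supervised")) {
    rep <- runRegime(dd$source, dd$target,
                     regimeSpec(r, k = if (r == "mixed") 1 else 0),
                     opts, 3)
    meta <- reportMeta(rep)
    audit <- meta$audit
    testCases <- meta$folds$target[[1]]$test
    labeled <- audit[audit$labelsUsed & audit$stage != "evaluate", ]
    touched <- unlist(strsplit(labeled$cases, ","))
    expect_length(intersect(testCases, touched), 0)
    # every case appears exactly once as test across the two folds
    tf <- meta$folds$target
    expect_setequal(c(tf[[1]]$test, tf[[2]]$test),
                    vapply(dd$target, caseId, character(1)))
  }
})

test_that("an identity translator makes adapted training equal baseline", {
  imgs <- renderSet(3, seedOff = 500)
  tc <- regTrainConfig(epochs = 2, seed = 9)
  spec <- regressorSpec(2, 2, 4)
  f1 <- trainRegressor(imgs[1:2], imgs[3], targetMapConfig(), spec, tc)
  f2 <- trainRegressor(translateImages(identity, imgs[1:2]),
                       translateImages(identity, imgs[3]),
                       targetMapConfig(), spec, tc)
  expect_identical(f1$log, f2$log)
  expect_identical(Ki67Adapt:::regGetParams(f1$model),
                   Ki67Adapt:::regGetParams(f2$model))
})

test_that("sweeps produce one row per setting and reduce as documented", {
  lp <- layoutParams()
  dd <- makeDomainDatasets(lp, styleParams(), targetStyleParams(), 6, 6, 79)
  opts <- microOpts()
  tab <- sweepTargetCount(dd$source, dd$target, ks = c(0, 1), opts = opts,
                          seeds = 4)
  expect_equal(nrow(tab), 2)
  adapted <- runRegime(dd$source, dd$target,
                       regimeSpec("adapted", sourceFraction = 0.4),
                       opts, 4)
  expect_equal(tab$f1Detection[tab$k == 0], detectionMetrics(adapted)$f1)
  tab2 <- sweepSourceFraction(dd$source, dd$target, fractions = 1,
                              opts = opts, seeds = 4)
  expect_equal(nrow(tab2), 1)
  full <- runRegime(dd$source, dd$target, regimeSpec("adapted"), opts, 4)
  expect_equal(tab2$f1Detection, detectionMetrics(full)$f1)
  expect_error(sweepSourceFraction(dd$source, dd$target, numeric(0),
                                   opts = opts), "empty")
})
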