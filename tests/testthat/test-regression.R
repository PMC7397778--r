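test_that("target maps put one Gaussian bump per annotation on its channel", {
  cfg <- targetMapConfig()
  z <- buildTargetMap(emptyAnnotations(), c(32, 32), cfg)
  expect_true(all(mapValues(z) == 0))

  one <- data.frame(row = 10L, col = 20L, label = "IPT")
  m <- mapValues(buildTargetMap(one, c(32, 40), cfg))
  expect_equal(dim(m), c(32, 40, 3))
  expect_equal(unname(m[11, 21, 1]), cfg$peak)
  expect_equal(which(m[, , 1] == max(m[, , 1])), 11 + 20 * 32)
  expect_true(all(m[, , 2:3] == 0))

  # two same-class bumps 2*radius apart equal the pixelwise max of singles
  two <- data.frame(row = c(10L, 10L), col = c(5L, 5L + 2L * cfg$radius),
                    label = "INT")
  both <- mapValues(buildTargetMap(two, c(40, 40), cfg))
  s1 <- mapValues(buildTargetMap(two[1, ], c(40, 40), cfg))
  s2 <- mapValues(buildTargetMap(two[2, ], c(40, 40), cfg))
  expect_equal(both, pmax(s1, s2))

  expect_error(buildTargetMap(data.frame(row = 50L, col = 1L,
                                         label = "NT"), c(32, 32), cfg),
               "bounds")
})

test_that("target-map local maxima count equals annotation count per class", {
  lp <- layoutParams(height = 96, width = 96, nIpt = 3, nInt = 4, nNt = 3,
                     minSeparation = 14)
  pc <- postprocessConfig(minSeparation = lp$minSeparation - 1)
  for (s in 1:4) {
    lay <- sampleLayout(lp, s)
    m <- mapValues(buildTargetMap(lay, c(96, 96)))
    for (cl in nucleusClasses()) {
      ch <- match(cl, nucleusClasses())
      peaks <- localMaxima(m[, , ch], pc)
      expect_equal(nrow(peaks), sum(lay$label == cl))
    }
  }
})

test_that("regression loss is the elementwise mean squared error", {
  set.seed(12)
  a <- array(runif(8 * 8 * 3), c(8, 8, 3))
  b <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(regressionLoss(a, a), 0)
  expect_equal(regressionLoss(array(0, c(4, 4, 3)), array(1, c(4, 4, 3))), 1)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(regressionLoss(a, b), acc / length(a))
  expect_equal(regressionLoss(a, b), regressionLoss(b, a))
  expect_error(regressionLoss(a, array(0, c(4, 4, 3))), "shape")
})

test_that("regressor output matches input dims with nonnegative responses", {
  R <- buildRegressor(regressorSpec(3, 3, 4), 5)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- predictMap(R, img)
  expect_s4_class(out, "OutputMap")
  expect_equal(dim(mapValues(out)), c(64, 64, 3))
  expect_gte(min(mapValues(out)), 0)
  # non-divisible tile sizes are padded and cropped internally
  odd <- array(runif(70 * 66 * 3), c(70, 66, 3))
  expect_equal(dim(mapValues(predictMap(R, odd))), c(70, 66, 3))
})

test_that("architecture switches change the parameter count", {
  n <- vapply(list(regressorSpec(2, 2, 4),
                   regressorSpec(2, 2, 4, skip = FALSE),
                   regressorSpec(2, 2, 4, fusion = FALSE),
                   regressorSpec(2, 2, 4, norm = "instance")),
              function(s) parameterCount(buildRegressor(s, 1)), numeric(1))
  expect_gt(n[1], n[2])
  expect_gt(n[1], n[3])
  expect_gt(n[4], n[1])
})

test_that("regressor training logs losses and can memorize two tiles", {
  imgs <- renderSet(2, seedOff = 400)
  spec <- regressorSpec(2, 2, 4)
  smoke <- trainRegressor(imgs, list(), targetMapConfig(), spec,
                          regTrainConfig(epochs = 1, seed = 1))
  expect_s3_class(smoke, "ki67RegressorFit")
  expect_equal(nrow(smoke$log), 1)
  expect_error(trainRegressor(list(), list(), targetMapConfig(), spec,
                              regTrainConfig()), "empty")

  fit <- trainRegressor(imgs, list(), targetMapConfig(), spec,
                        regTrainConfig(epochs = 20, seed = 1))
  expect_lt(fit$log$train[20], fit$log$train[1])
})
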