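test_that("cycle loss is the mean absolute difference", {
  set.seed(11)
  x <- array(runif(6 * 6 * 3), c(6, 6, 3))
  expect_equal(cycleLoss(x, x), 0)
  expect_equal(cycleLoss(array(0, c(4, 4, 3)), array(1, c(4, 4, 3))), 1)
  y <- array(runif(6 * 6 * 3), c(6, 6, 3))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + abs(x[i] - y[i])
  expect_equal(cycleLoss(x, y), acc / length(x))
  expect_error(cycleLoss(x, array(0, c(5, 5, 3))), "shape")
})

test_that("least-squares adversarial losses have the stated fixed points", {
  expect_equal(adversarialLosses(rep(1, 9), rep(0, 9))$lossD, 0)
  expect_equal(adversarialLosses(rep(0.3, 4), rep(1, 4))$lossG, 0)
  l <- adversarialLosses(0.5, 0.5)
  expect_equal(l$lossD, 0.25)
  expect_equal(l$lossG, 0.25)
  expect_error(adversarialLosses(c(1, NaN), c(0, 0)), "finite")
})

test_that("generator maps images to same-shape images deterministically", {
  expect_error(generatorSpec(blocks = 0))
  G <- buildGenerator(generatorSpec(blocks = 2, baseWidth = 4), 3)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  y1 <- applyGenerator(G, img)
  expect_equal(dim(y1), c(64, 64, 3))
  expect_true(all(y1 >= 0 & y1 <= 1))
  expect_identical(y1, applyGenerator(G, img))
  # odd sizes are padded internally and cropped back
  odd <- array(runif(70 * 66 * 3), c(70, 66, 3))
  expect_equal(dim(applyGenerator(G, odd)), c(70, 66, 3))
})

test_that("PatchGAN discriminator emits a patch score map", {
  spec <- discriminatorSpec()
  expect_equal(receptiveField(spec), 70)
  D <- buildDiscriminator(spec, 4)
  expect_equal(dim(applyDiscriminator(D, array(0.5, c(70, 70, 3)))),
               c(1, 1))
  out <- applyDiscriminator(D, array(0.5, c(140, 140, 3)))
  expect_gt(prod(dim(out)), 1)
})

test_that("perturbation probe recovers the analytic receptive field", {
  # reduced configuration: cheap, and checks the prober itself
  spec <- discriminatorSpec(baseWidth = 8, kernels = c(4, 4, 4),
                            strides = c(2, 2, 1))
  expect_equal(receptiveField(spec), 22)
  D <- buildDiscriminator(spec, 2)
  rf <- measureReceptiveField(D, inputSize = 40, unit = c(2, 2))
  expect_equal(unname(rf), c(22, 22))
})

test_that("translation preserves annotations, case ids and shapes", {
  imgs <- renderSet(5, seedOff = 300)
  idT <- translateImages(identity, imgs)
  expect_identical(lapply(idT, pixels), lapply(imgs, pixels))
  expect_identical(lapply(idT, annotations), lapply(imgs, annotations))

  G <- buildGenerator(generatorSpec(blocks = 1, baseWidth = 4), 5)
  tr <- translateImages(G, imgs)
  expect_length(tr, 5)
  expect_identical(lapply(tr, annotations), lapply(imgs, annotations))
  expect_identical(vapply(tr, caseId, character(1)),
                   vapply(imgs, caseId, character(1)))
  expect_identical(dim(pixels(tr[[1]])), dim(pixels(imgs[[1]])))
})

test_that("cycle-GAN training runs, logs losses and reduces cycle error", {
  src <- renderSet(2, seedOff = 310)
  tgt <- renderSet(2, targetStyleParams(), seedOff = 320)
  spec <- generatorSpec(blocks = 1, baseWidth = 4)
  dspec <- discriminatorSpec(baseWidth = 8, kernels = c(4, 4, 4),
                             strides = c(2, 2, 1))
  one <- trainCycleGAN(src, tgt, ganTrainConfig(iterations = 1, seed = 2),
                       spec, dspec)
  expect_s3_class(one, "ki67CycleGAN")
  expect_equal(nrow(one$trace), 1)
  expect_error(trainCycleGAN(list(), tgt, ganTrainConfig(), spec, dspec),
               "non-empty")

  # identical source and target with a strong cycle weight: the logged
  # cycle reconstruction loss should trend down
  gan <- trainCycleGAN(src, src,
                       ganTrainConfig(iterations = 30, lambdaCycle = 20,
                                      seed = 3), spec, dspec)
  expect_lt(mean(tail(gan$trace$cycle, 5)), mean(head(gan$trace$cycle, 5)))
})

test_that("a reduced generator trains within a smoke-test budget", {
  src <- renderSet(4, seedOff = 330)
  tgt <- renderSet(4, targetStyleParams(), seedOff = 340)
  t0 <- Sys.time()
  gan <- trainCycleGAN(src, tgt, ganTrainConfig(iterations = 50, seed = 4),
                       generatorSpec(blocks = 2, baseWidth = 8),
                       discriminatorSpec(baseWidth = 8, kernels = c(4, 4, 4),
                                         strides = c(2, 2, 1)))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_equal(nrow(gan$trace), 50)
  expect_lt(elapsed, 60)
})
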