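test_that("suppression zeroes sub-threshold responses and is idempotent", {
  m <- matrix(c(0.2, 0.5, 0.9, 0.9), 2, 2)
  expect_identical(suppressMap(m, 0), m)
  expect_equal(suppressMap(matrix(c(0.2, 0.5, 0.9, 0.9), 2, 2,
                                  byrow = TRUE), 1),
               matrix(c(0, 0, 0.9, 0.9), 2, 2, byrow = TRUE))
  z <- matrix(0, 3, 3)
  expect_identical(suppressMap(z, 0.7), z)
  expect_error(suppressMap(m, 1.5), "eta")
  for (s in 1:5) {
    r <- randomMap(12, 12, s)
    eta <- runif(1)
    expect_identical(suppressMap(suppressMap(r, eta), eta),
                     suppressMap(r, eta))
  }
})

test_that("local maxima match the definitional brute-force scan", {
  cfg <- postprocessConfig(neighborhood = 3, minSeparation = 3)
  one <- matrix(0, 7, 7); one[3, 5] <- 0.4
  expect_equal(localMaxima(one, cfg),
               data.frame(row = 2L, col = 4L, value = 0.4))

  # two Gaussian bumps 6 px apart on a 9 x 9 grid
  g <- function(r0, c0) outer(0:8, 0:8, function(r, c)
    exp(-((r - r0)^2 + (c - c0)^2) / 4))
  bumps <- pmax(g(2, 2), g(2, 8))
  pk <- localMaxima(bumps, cfg)
  expect_equal(nrow(pk), 2)
  expect_setequal(paste(pk$row, pk$col), c("2 2", "2 8"))

  plateau <- matrix(1, 6, 6)
  pk <- localMaxima(plateau, cfg)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$row, pk$col), c(0, 0))

  for (s in 1:8) {
    r <- randomMap(15, 15, s, sparsity = 0.5)
    got <- localMaxima(r, cfg)
    want <- bruteLocalMaxima(r, cfg$neighborhood, cfg$minSeparation)
    expect_equal(got$row, want$row, label = sprintf("seed %d rows", s))
    expect_equal(got$col, want$col, label = sprintf("seed %d cols", s))
    expect_equal(got$value, want$value)
  }
})

test_that("channel merging takes the pixelwise maximum", {
  a <- matrix(runif(16), 4, 4)
  m <- array(0, c(4, 4, 3)); m[, , 1] <- a
  expect_equal(mergeChannels(m), a)
  v <- array(0, c(1, 1, 3)); v[1, 1, ] <- c(0.1, 0.7, 0.3)
  expect_equal(mergeChannels(v)[1, 1], 0.7)
  r <- array(runif(4 * 4 * 3), c(4, 4, 3))
  mg <- mergeChannels(r)
  for (ch in 1:3) expect_true(all(mg >= r[, , ch]))
})

test_that("point classification is channel argmax with IPT>INT>NT ties", {
  v <- array(0, c(3, 3, 3))
  v[2, 2, ] <- c(0.9, 0.1, 0)
  expect_equal(classifyPoint(v, c(1, 1)), "IPT")
  v[2, 2, ] <- c(0.4, 0.4, 0.1)
  expect_equal(classifyPoint(v, c(1, 1)), "IPT")
  v[2, 2, ] <- c(0.1, 0.3, 0.3)
  expect_equal(classifyPoint(v, c(1, 1)), "INT")
  expect_error(classifyPoint(v, c(5, 1)), "bounds")
})

test_that("detection recovers well-separated target-map annotations", {
  expect_equal(nrow(detectNuclei(array(0, c(16, 16, 3)))), 0)

  lp <- layoutParams(height = 96, width = 96, nIpt = 2, nInt = 3, nNt = 2,
                     minSeparation = 26)
  lay <- sampleLayout(lp, 17)
  det <- detectNuclei(buildTargetMap(lay, c(96, 96)),
                      postprocessConfig(eta = 0.5))
  expect_equal(nrow(det), 7)
  o1 <- order(det$row, det$col); o2 <- order(lay$row, lay$col)
  expect_equal(det$row[o1], lay$row[o2])
  expect_equal(det$col[o1], lay$col[o2])
  expect_equal(det$label[o1], lay$label[o2])

  # reported label always matches the channel argmax at the peak
  om <- randomOutputMap(24, 24, 3)
  det <- detectNuclei(om, postprocessConfig(eta = 0.2))
  for (i in seq_len(nrow(det)))
    expect_equal(det$label[i], classifyPoint(om, c(det$row[i], det$col[i])))
})

test_that("detection count is non-increasing in eta", {
  for (s in 1:6) {
    om <- randomOutputMap(20, 20, s)
    counts <- vapply(seq(0, 1, by = 0.1), function(eta)
      nrow(detectNuclei(om, postprocessConfig(eta = eta))), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  # per-channel suppression mode is also monotone and runs
  om <- randomOutputMap(20, 20, 99)
  counts <- vapply(seq(0, 1, by = 0.2), function(eta)
    nrow(detectNuclei(om, postprocessConfig(eta = eta, perChannel = TRUE))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})
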