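# Numerical gradient checks of the CNN engine against central finite
# differences: the whole training stack rests on these adjoints.

numGrad <- function(f, x, dy, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (sum(f(xp) * dy) - sum(f(xm) * dy)) / (2 * eps)
  }, numeric(1))
}

test_that("layer backward passes match finite differences", {
  set.seed(41)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  layers <- list(
    conv_zero = Ki67Adapt:::lyConv(2, 3, 3, 1, 1, "zero"),
    conv_reflect_s2 = Ki67Adapt:::lyConv(2, 3, 3, 2, 1, "reflect"),
    conv_k7 = Ki67Adapt:::lyConv(2, 2, 7, 1, 3, "reflect"),
    inorm = Ki67Adapt:::lyINorm(2),
    lrelu = Ki67Adapt:::lyAct("lrelu"),
    tanh = Ki67Adapt:::lyAct("tanh"),
    up = Ki67Adapt:::lyUp(2),
    res = Ki67Adapt:::lyRes(2))
  for (nm in names(layers)) {
    l <- layers[[nm]]
    fw <- Ki67Adapt:::layerForward(l, x)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bk <- Ki67Adapt:::layerBackward(l, fw$cache, dy)
    idx <- sample(length(x), 6)
    num <- numGrad(function(z) Ki67Adapt:::layerForward(l, z)$y, x, dy, idx)
    expect_equal(unname(bk$dx[idx]), num, tolerance = 1e-5, label = nm)
  }
})

test_that("convolution weight and bias gradients match finite differences", {
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  l <- Ki67Adapt:::lyConv(2, 3, 3, 1, 1, "reflect")
  fw <- Ki67Adapt:::layerForward(l, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- Ki67Adapt:::layerBackward(l, fw$cache, dy)
  idx <- sample(length(l$W), 5)
  num <- vapply(idx, function(i) {
    lp <- l; lp$W[i] <- lp$W[i] + 1e-5
    lm <- l; lm$W[i] <- lm$W[i] - 1e-5
    (sum(Ki67Adapt:::layerForward(lp, x)$y * dy) -
       sum(Ki67Adapt:::layerForward(lm, x)$y * dy)) / 2e-5
  }, numeric(1))
  expect_equal(unname(bk$grads$W[idx]), num, tolerance = 1e-5)
  numB <- vapply(seq_along(l$b), function(i) {
    lp <- l; lp$b[i] <- lp$b[i] + 1e-5
    lm <- l; lm$b[i] <- lm$b[i] - 1e-5
    (sum(Ki67Adapt:::layerForward(lp, x)$y * dy) -
       sum(Ki67Adapt:::layerForward(lm, x)$y * dy)) / 2e-5
  }, numeric(1))
  expect_equal(unname(bk$grads$b), numB, tolerance = 1e-5)
})

test_that("full regressor backward matches finite differences", {
  set.seed(43)
  R <- buildRegressor(regressorSpec(2, 2, 4), 7)
  x <- array(rnorm(16 * 16 * 3, 0, 0.5), c(16, 16, 3))
  fw <- Ki67Adapt:::regForward(R, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- Ki67Adapt:::regBackward(R, fw$caches, dy)
  idx <- sample(length(x), 6)
  num <- numGrad(function(z) Ki67Adapt:::regForward(R, z)$y, x, dy, idx)
  expect_equal(unname(bk$dx[idx]), num, tolerance = 1e-4)
})

test_that("instance-normalized regressor variant also backpropagates", {
  set.seed(44)
  R <- buildRegressor(regressorSpec(2, 2, 4, norm = "instance"), 8)
  x <- array(rnorm(16 * 16 * 3, 0, 0.5), c(16, 16, 3))
  fw <- Ki67Adapt:::regForward(R, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- Ki67Adapt:::regBackward(R, fw$caches, dy)
  idx <- sample(length(x), 4)
  num <- numGrad(function(z) Ki67Adapt:::regForward(R, z)$y, x, dy, idx)
  expect_equal(unname(bk$dx[idx]), num, tolerance = 1e-4)
})
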