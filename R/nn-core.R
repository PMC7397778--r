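# Compact CPU CNN engine. Feature maps are plain H x W x C double arrays;
# convolutions run as im2col + BLAS GEMM through the C++ kernels. Layers are
# tagged lists; networks are lists of layers with explicit forward/backward
# passes and an Adam optimizer over the (nested) parameter trees. Everything
# is deterministic given the RNG state at build time and the data order.

padTypeInt <- function(padType) switch(padType, zero = 0L, reflect = 1L,
                                       stop("unknown pad type"))

lyConv <- function(cin, cout, k, stride = 1, pad = 0, padType = "zero",
                   init = c("gauss", "he")) {
  init <- match.arg(init)
  sd <- if (init == "gauss") 0.02 else sqrt(2 / (k * k * cin))
  list(type = "conv",
       W = matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), padType = padTypeInt(padType),
       cin = as.integer(cin), cout = as.integer(cout))
}

lyINorm <- function(c) {
  list(type = "inorm", gamma = rep(1, c), beta = numeric(c), eps = 1e-5)
}

lyAct <- function(kind, alpha = 0.2) list(type = "act", kind = kind,
                                          alpha = alpha)

lyUp <- function(factor = 2) list(type = "up", factor = as.integer(factor))

lyRes <- function(width, padType = "reflect", init = "gauss", norm = TRUE,
                  act = "relu") {
  sub <- if (norm)
    list(lyConv(width, width, 3, 1, 1, padType, init), lyINorm(width),
         lyAct(act, 0.1),
         lyConv(width, width, 3, 1, 1, padType, init), lyINorm(width))
  else {
    # without normalization, zero-init the residual branch output so the
    # block starts as the identity (Fixup-style), keeping activations and
    # gradients well-scaled at depth
    cv2 <- lyConv(width, width, 3, 1, 1, padType, init)
    cv2$W <- cv2$W * 0
    list(lyConv(width, width, 3, 1, 1, padType, init), lyAct(act, 0.1), cv2)
  }
  list(type = "res", sub = sub)
}

convForward <- function(l, x) {
  d <- dim(x)
  xp <- cpp_pad(x, l$pad, l$padType)
  col <- cpp_im2col(xp, l$k, l$stride)
  y2 <- col %*% l$W
  y2 <- sweep(y2, 2, l$b, "+")
  outH <- (dim(xp)[1] - l$k) %/% l$stride + 1
  outW <- (dim(xp)[2] - l$k) %/% l$stride + 1
  list(y = array(y2, c(outH, outW, l$cout)),
       cache = list(col = col, H = d[1], W = d[2],
                    Hp = dim(xp)[1], Wp = dim(xp)[2]))
}

convBackward <- function(l, cache, dy) {
  d <- dim(dy)
  dy2 <- matrix(dy, d[1] * d[2], d[3])
  dW <- crossprod(cache$col, dy2)
  db <- colSums(dy2)
  dcol <- tcrossprod(dy2, l$W)
  dxp <- cpp_col2im(dcol, cache$Hp, cache$Wp, l$cin, l$k, l$stride)
  dx <- cpp_unpad(dxp, cache$H, cache$W, l$pad, l$padType)
  list(dx = dx, grads = list(W = dW, b = db))
}

inormForward <- function(l, x) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu * mu
  invs <- 1 / sqrt(va + l$eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invs, "*")
  ym <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
  list(y = array(ym, d), cache = list(xhat = xhat, invs = invs, d = d))
}

inormBackward <- function(l, cache, dy) {
  d <- cache$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, l$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dxm <- sweep(sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*"),
               2, cache$invs, "*")
  list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
}

actForward <- function(l, x) {
  y <- switch(l$kind,
              relu = pmax(x, 0),
              lrelu = ifelse(x > 0, x, l$alpha * x),
              tanh = tanh(x),
              stop("unknown activation"))
  list(y = y, cache = if (l$kind == "tanh") y else x)
}

actBackward <- function(l, cache, dy) {
  dx <- switch(l$kind,
               relu = dy * (cache > 0),
               lrelu = dy * ifelse(cache > 0, 1, l$alpha),
               tanh = dy * (1 - cache * cache))
  list(dx = dx, grads = NULL)
}

upForward <- function(l, x) {
  d <- dim(x)
  f <- l$factor
  y <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
         drop = FALSE]
  list(y = y, cache = d)
}

upBackward <- function(l, cache, dy) {
  d <- cache
  f <- l$factor
  fH <- d[1] * f; fW <- d[2] * f; C <- d[3]
  s1 <- rowsum(matrix(dy, fH, fW * C), rep(seq_len(d[1]), each = f))
  a1 <- array(s1, c(d[1], fW, C))
  s2 <- rowsum(matrix(aperm(a1, c(2, 1, 3)), fW, d[1] * C),
               rep(seq_len(d[2]), each = f))
  dx <- aperm(array(s2, c(d[2], d[1], C)), c(2, 1, 3))
  list(dx = dx, grads = NULL)
}

layerForward <- function(l, x) {
  switch(l$type,
         conv = convForward(l, x),
         inorm = inormForward(l, x),
         act = actForward(l, x),
         up = upForward(l, x),
         res = {
           s <- netForward(l$sub, x)
           list(y = x + s$y, cache = s$caches)
         })
}

layerBackward <- function(l, cache, dy) {
  switch(l$type,
         conv = convBackward(l, cache, dy),
         inorm = inormBackward(l, cache, dy),
         act = actBackward(l, cache, dy),
         up = upBackward(l, cache, dy),
         res = {
           r <- netBackward(l$sub, cache, dy)
           list(dx = dy + r$dx, grads = r$grads)
         })
}

netForward <- function(net, x) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    f <- layerForward(net[[i]], x)
    x <- f$y
    caches[[i]] <- f$cache
  }
  list(y = x, caches = caches)
}

netBackward <- function(net, caches, dy) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    b <- layerBackward(net[[i]], caches[[i]], dy)
    dy <- b$dx
    grads[i] <- list(b$grads)
  }
  list(dx = dy, grads = grads)
}

# ---- parameter trees -------------------------------------------------------

layerGetParams <- function(l) {
  switch(l$type,
         conv = list(W = l$W, b = l$b),
         inorm = list(gamma = l$gamma, beta = l$beta),
         res = lapply(l$sub, layerGetParams),
         NULL)
}

layerSetParams <- function(l, p) {
  switch(l$type,
         conv = { l$W <- p$W; l$b <- p$b; l },
         inorm = { l$gamma <- p$gamma; l$beta <- p$beta; l },
         res = { l$sub <- mapply(layerSetParams, l$sub, p, SIMPLIFY = FALSE); l },
         l)
}

netGetParams <- function(net) lapply(net, layerGetParams)
netSetParams <- function(net, p) mapply(layerSetParams, net, p,
                                        SIMPLIFY = FALSE)

treeZero <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, treeZero))
  p * 0
}

treeAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(treeAdd, a, b, SIMPLIFY = FALSE))
  a + b
}

treeScale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, treeScale, s = s))
  a * s
}

treeCount <- function(p) {
  if (is.null(p)) return(0)
  if (is.list(p)) return(sum(vapply(p, treeCount, numeric(1))))
  length(p)
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) list(m = treeZero(params), v = treeZero(params),
                                  t = 0L)

adamLeaf <- function(p, g, m, v, lr, b1, b2, eps, t) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  list(p = p, m = m, v = v)
}

adamTree <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.null(g)) return(list(p = p, m = m, v = v))
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adamTree(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, eps, t)
      p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
    }
    return(list(p = p, m = m, v = v))
  }
  adamLeaf(p, g, m, v, lr, b1, b2, eps, t)
}

adamUpdate <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  p <- netGetParams(net)
  r <- adamTree(p, grads, state$m, state$v, lr, beta1, beta2, eps, state$t)
  state$m <- r$m; state$v <- r$v
  list(net = netSetParams(net, r$p), state = state)
}

#' Number of trainable parameters of a model
#'
#' Counts every convolution weight/bias and normalization scale/offset in a
#' generator, discriminator or regressor built by this package. Useful for
#' checking that architectural switches (skip connections, fusion) change
#' the model as intended.
#' @param model a model returned by [buildGenerator()],
#'   [buildDiscriminator()] or [buildRegressor()].
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  nets <- model$nets
  if (is.null(nets)) nets <- list(model$net)
  sum(vapply(nets, function(n) treeCount(netGetParams(n)), numeric(1)))
}

# Nearest-neighbour resize of an H x W x C array by integer factor f.
upsampleNearest <- function(x, f) {
  if (f == 1) return(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
    drop = FALSE]
}

# Adjoint of upsampleNearest (block sum).
downsampleSum <- function(dy, f) {
  if (f == 1) return(dy)
  d <- dim(dy)
  H <- d[1] %/% f; W <- d[2] %/% f; C <- d[3]
  s1 <- rowsum(matrix(dy, d[1], d[2] * C), rep(seq_len(H), each = f))
  a1 <- array(s1, c(H, d[2], C))
  s2 <- rowsum(matrix(aperm(a1, c(2, 1, 3)), d[2], H * C),
               rep(seq_len(W), each = f))
  aperm(array(s2, c(W, H, C)), c(2, 1, 3))
}

# Reflect-pad an H x W x C array on the bottom/right so both spatial dims
# become multiples of m; returns the padded array and the original dims.
padToMultiple <- function(x, m) {
  d <- dim(x)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  if (ph == 0 && pw == 0) return(list(x = x, H = d[1], W = d[2]))
  ri <- c(seq_len(d[1]), d[1] - seq_len(ph))
  ci <- c(seq_len(d[2]), d[2] - seq_len(pw))
  list(x = x[ri, ci, , drop = FALSE], H = d[1], W = d[2])
}

cropTo <- function(x, H, W) x[seq_len(H), seq_len(W), , drop = FALSE]
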