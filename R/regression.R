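# Proximity-map regression: Gaussian target-map construction from point
# annotations, the residual encoder-decoder regressor with long-range skip
# connections and multi-level fusion, and its MSE training loop.

#' Build a Gaussian proximity target map from annotations
#'
#' Each annotation contributes, on its class channel, a Gaussian bump of
#' height `peak` and scale `sigma`, truncated at `radius` pixels;
#' overlapping bumps combine by pixelwise maximum, so every nucleus keeps
#' exactly one strict local maximum at its annotated center.
#'
#' @param annotations data.frame with 0-based `row`, `col` and `label`.
#' @param dims length-2 (H, W).
#' @param config a [targetMapConfig()].
#' @return an [OutputMap-class].
#' @export
buildTargetMap <- function(annotations, dims, config = targetMapConfig()) {
  stopifnot(inherits(config, "TargetMapConfig"), length(dims) == 2)
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  ann <- as.data.frame(annotations)
  vals <- array(0, c(H, W, 3))
  if (nrow(ann)) {
    checkLabels(ann$label)
    if (any(ann$row < 0 | ann$row >= H | ann$col < 0 | ann$col >= W))
      stop("annotation outside map bounds")
    ext <- ceiling(config$radius)
    for (i in seq_len(nrow(ann))) {
      ch <- match(ann$label[i], nucleusClasses())
      rc <- ann$row[i] + 1L; cc <- ann$col[i] + 1L
      r0 <- max(1L, rc - ext); r1 <- min(H, rc + ext)
      c0 <- max(1L, cc - ext); c1 <- min(W, cc + ext)
      dr <- matrix((r0:r1) - rc, r1 - r0 + 1, c1 - c0 + 1)
      dc <- matrix((c0:c1) - cc, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
      d2 <- dr * dr + dc * dc
      bump <- config$peak * exp(-d2 / (2 * config$sigma^2))
      bump[d2 > config$radius^2] <- 0
      vals[r0:r1, c0:c1, ch] <- pmax(vals[r0:r1, c0:c1, ch], bump)
    }
  }
  OutputMap(vals)
}

#' Pixelwise mean-squared regression loss
#'
#' @param prediction,target [OutputMap-class] objects or arrays of
#'   identical shape.
#' @return nonnegative scalar; zero iff the maps are equal.
#' @export
regressionLoss <- function(prediction, target) {
  p <- if (is(prediction, "OutputMap")) mapValues(prediction) else prediction
  t <- if (is(target, "OutputMap")) mapValues(target) else target
  if (!identical(dim(p), dim(t))) stop("shape mismatch")
  mean((p - t)^2)
}

# Widths per encoder level: double each stage, capped at 8x base.
regWidths <- function(spec) {
  w <- spec$baseWidth
  pmin(w * 2^seq_len(spec$encoderBlocks), 8 * w)
}

#' Build the proximity-map regressor
#'
#' Residual encoder-decoder: a 3x3 stem, `encoderBlocks` stages of
#' (stride-2 convolution + residual block), a mirrored decoder whose
#' stages upsample, optionally concatenate the encoder feature at the same
#' scale (long-range skip connections), and apply a residual block. With
#' fusion on, decoder features from every level are resized to full
#' resolution and concatenated before a 2-convolution head with a
#' rectified 3-channel output, so the model can integrate evidence across
#' scales. Arbitrary tile sizes are handled by reflective padding to a
#' multiple of the total downsampling factor and cropping back.
#'
#' @param spec a [regressorSpec()].
#' @param seed integer seed for weight initialization.
#' @return a regressor model (list with class `ki67Regressor`); apply it
#'   with [predictMap()].
#' @export
buildRegressor <- function(spec, seed) {
  stopifnot(inherits(spec, "RegressorSpec"))
  w <- spec$baseWidth
  widths <- regWidths(spec)
  E <- spec$encoderBlocks
  useNorm <- spec$norm %in% c("instance", "interior")
  stemNorm <- spec$norm == "instance"
  maybeNorm <- function(c) if (useNorm) list(lyINorm(c)) else list()
  # without normalization a fully dead ReLU layer cannot recover, so the
  # norm-free network uses leaky activations throughout
  actKind <- if (useNorm) "relu" else "lrelu"
  model <- withSeed(seed, {
    stem <- c(list(lyConv(3, w, 3, 1, 1, "reflect", "he")),
              if (stemNorm) list(lyINorm(w)) else list(),
              list(lyAct(actKind, 0.1)))
    enc <- lapply(seq_len(E), function(i) {
      cin <- if (i == 1) w else widths[i - 1]
      list(down = c(list(lyConv(cin, widths[i], 3, 2, 1, "zero", "he")),
                    maybeNorm(widths[i]), list(lyAct(actKind, 0.1))),
           res = list(lyRes(widths[i], "reflect", "he", useNorm, actKind)))
    })
    dec <- lapply(rev(seq_len(E)), function(i) {
      cout <- if (i == 1) w else widths[i - 1]
      cin <- widths[i]
      mergeIn <- if (spec$skip) cout + cout else cout
      list(up = c(list(lyUp(2), lyConv(cin, cout, 3, 1, 1, "zero", "he")),
                  maybeNorm(cout), list(lyAct(actKind, 0.1))),
           merge = if (spec$skip)
             c(list(lyConv(mergeIn, cout, 3, 1, 1, "reflect", "he")),
               maybeNorm(cout), list(lyAct(actKind, 0.1))),
           res = list(lyRes(cout, "reflect", "he", useNorm, actKind)))
    })
    headIn <- if (spec$fusion) sum(c(w, widths[seq_len(E - 1)])) else w
    # linear output head: the rectification that guarantees nonnegative
    # maps is applied at prediction time, so the training gradient can
    # never die globally the way a saturated final ReLU can
    out <- lyConv(w, 3, 3, 1, 1, "reflect", "he")
    out$W <- out$W * 0.2
    head <- c(list(lyConv(headIn, w, 3, 1, 1, "reflect", "he")),
              maybeNorm(w), list(lyAct(actKind, 0.1), out))
    list(stem = stem, enc = enc, dec = dec, head = head)
  })
  nets <- c(list(model$stem),
            unlist(lapply(model$enc, function(e) list(e$down, e$res)),
                   recursive = FALSE),
            unlist(lapply(model$dec, function(d)
              Filter(Negate(is.null), list(d$up, d$merge, d$res))),
              recursive = FALSE),
            list(model$head))
  structure(list(model = model, spec = spec, seed = seed, nets = nets),
            class = "ki67Regressor")
}

# Forward pass through the regressor in network space. Returns the output
# and every cache needed for backprop. x dims must be divisible by 2^E.
regForward <- function(R, x) {
  m <- R$model; spec <- R$spec; E <- spec$encoderBlocks
  cs <- list()
  s <- netForward(m$stem, x)
  cs$stem <- s$caches
  skips <- list(s$y)                     # encoder features per scale (pre-down)
  h <- s$y
  cs$enc <- vector("list", E)
  for (i in seq_len(E)) {
    dwn <- netForward(m$enc[[i]]$down, h)
    rs <- netForward(m$enc[[i]]$res, dwn$y)
    cs$enc[[i]] <- list(down = dwn$caches, res = rs$caches)
    h <- rs$y
    if (i < E) skips[[i + 1]] <- h
  }
  cs$dec <- vector("list", E)
  fused <- list()
  for (j in seq_len(E)) {               # decoder stage j works at level E-j
    lev <- E - j + 1
    up <- netForward(m$dec[[j]]$up, h)
    h <- up$y
    ccache <- NULL
    if (spec$skip) {
      sk <- skips[[lev]]
      ccache <- c(dim(h)[3], dim(sk)[3])
      h <- array(c(h, sk), c(dim(h)[1], dim(h)[2], ccache[1] + ccache[2]))
      mg <- netForward(m$dec[[j]]$merge, h)
      h <- mg$y
    } else mg <- NULL
    rs <- netForward(m$dec[[j]]$res, h)
    h <- rs$y
    cs$dec[[j]] <- list(up = up$caches,
                        merge = if (!is.null(mg)) mg$caches,
                        cdim = ccache, res = rs$caches)
    fused[[j]] <- h
  }
  if (spec$fusion) {
    # resize all decoder outputs except the last to full resolution
    full <- dim(h)[1:2]
    factors <- 2^((E - 1):0)
    parts <- lapply(seq_len(E), function(j)
      upsampleNearest(fused[[j]], factors[j]))
    widths <- vapply(parts, function(p) dim(p)[3], numeric(1))
    hIn <- array(unlist(parts), c(full[1], full[2], sum(widths)))
    cs$fuse <- list(factors = factors, widths = widths)
  } else hIn <- h
  hd <- netForward(m$head, hIn)
  cs$head <- hd$caches
  list(y = hd$y, caches = cs)
}

# Backward pass mirroring regForward; returns the gradient trees grouped
# exactly like the model (stem/enc/dec/head).
regBackward <- function(R, caches, dy) {
  m <- R$model; spec <- R$spec; E <- spec$encoderBlocks
  g <- list()
  bh <- netBackward(m$head, caches$head, dy)
  g$head <- bh$grads
  dIn <- bh$dx
  dFused <- vector("list", E)
  if (spec$fusion) {
    f <- caches$fuse
    off <- 0
    for (j in seq_len(E)) {
      wj <- f$widths[j]
      dPart <- dIn[, , off + seq_len(wj), drop = FALSE]
      dFused[[j]] <- downsampleSum(dPart, f$factors[j])
      off <- off + wj
    }
    dh <- dFused[[E]]
  } else dh <- dIn
  g$dec <- vector("list", E)
  dSkips <- vector("list", E)
  for (j in rev(seq_len(E))) {
    lev <- E - j + 1
    if (spec$fusion && j < E) dh <- dh + dFused[[j]]
    cj <- caches$dec[[j]]
    br <- netBackward(m$dec[[j]]$res, cj$res, dh)
    dh <- br$dx
    gm <- NULL
    if (spec$skip) {
      bm <- netBackward(m$dec[[j]]$merge, cj$merge, dh)
      gm <- bm$grads
      c1 <- cj$cdim[1]
      dSkips[[lev]] <- bm$dx[, , c1 + seq_len(cj$cdim[2]), drop = FALSE]
      dh <- bm$dx[, , seq_len(c1), drop = FALSE]
    }
    bu <- netBackward(m$dec[[j]]$up, cj$up, dh)
    g$dec[[j]] <- list(up = bu$grads, merge = gm, res = br$grads)
    dh <- bu$dx
  }
  g$enc <- vector("list", E)
  for (i in rev(seq_len(E))) {
    if (i < E && !is.null(dSkips[[i + 1]])) dh <- dh + dSkips[[i + 1]]
    ci <- caches$enc[[i]]
    br <- netBackward(m$enc[[i]]$res, ci$res, dh)
    bd <- netBackward(m$enc[[i]]$down, ci$down, br$dx)
    g$enc[[i]] <- list(down = bd$grads, res = br$grads)
    dh <- bd$dx
  }
  if (!is.null(dSkips[[1]])) dh <- dh + dSkips[[1]]
  bs <- netBackward(m$stem, caches$stem, dh)
  g$stem <- bs$grads
  # order must mirror regGetParams for the positional optimizer walk
  list(grads = g[c("stem", "enc", "dec", "head")], dx = bs$dx)
}

regGetParams <- function(R) {
  m <- R$model
  list(stem = netGetParams(m$stem),
       enc = lapply(m$enc, function(e) list(down = netGetParams(e$down),
                                            res = netGetParams(e$res))),
       dec = lapply(m$dec, function(d) list(
         up = netGetParams(d$up),
         merge = if (!is.null(d$merge)) netGetParams(d$merge),
         res = netGetParams(d$res))),
       head = netGetParams(m$head))
}

regSetParams <- function(R, p) {
  m <- R$model
  m$stem <- netSetParams(m$stem, p$stem)
  for (i in seq_along(m$enc)) {
    m$enc[[i]]$down <- netSetParams(m$enc[[i]]$down, p$enc[[i]]$down)
    m$enc[[i]]$res <- netSetParams(m$enc[[i]]$res, p$enc[[i]]$res)
  }
  for (j in seq_along(m$dec)) {
    m$dec[[j]]$up <- netSetParams(m$dec[[j]]$up, p$dec[[j]]$up)
    if (!is.null(m$dec[[j]]$merge))
      m$dec[[j]]$merge <- netSetParams(m$dec[[j]]$merge, p$dec[[j]]$merge)
    m$dec[[j]]$res <- netSetParams(m$dec[[j]]$res, p$dec[[j]]$res)
  }
  m$head <- netSetParams(m$head, p$head)
  R$model <- m
  R$nets <- c(list(m$stem),
              unlist(lapply(m$enc, function(e) list(e$down, e$res)),
                     recursive = FALSE),
              unlist(lapply(m$dec, function(d)
                Filter(Negate(is.null), list(d$up, d$merge, d$res))),
                recursive = FALSE),
              list(m$head))
  R
}

#' Predict a proximity map for an image
#'
#' @param R a `ki67Regressor`.
#' @param image an [AnnotatedImage-class] or H x W x 3 array in [0, 1].
#' @return an [OutputMap-class] with the same spatial dims as the input;
#'   responses are nonnegative by construction (rectified output head).
#' @export
predictMap <- function(R, image) {
  stopifnot(inherits(R, "ki67Regressor"))
  img <- if (is(image, "AnnotatedImage")) pixels(image) else image
  p <- padToMultiple(toNet(img), 2^R$spec$encoderBlocks)
  y <- regForward(R, p$x)$y
  OutputMap(pmax(cropTo(y, p$H, p$W), 0))
}

#' Train the proximity-map regressor
#'
#' Adam on the pixelwise MSE between predicted and Gaussian target maps,
#' one image per step in a seeded order. Images without annotations
#' contribute an all-zero target. After each epoch the validation loss is
#' computed (falling back to the training loss when no validation images
#' are given) and the weights with the best validation loss are returned.
#'
#' @param trainImages non-empty list of [AnnotatedImage-class] objects.
#' @param valImages list of validation images (may be empty).
#' @param targetConfig a [targetMapConfig()].
#' @param spec a [regressorSpec()].
#' @param trainConfig a [regTrainConfig()].
#' @return list of class `ki67RegressorFit` with elements `model` (the
#'   best-validation `ki67Regressor`), `log` (per-epoch train/val losses)
#'   and `bestEpoch`.
#' @export
trainRegressor <- function(trainImages, valImages = list(),
                           targetConfig = targetMapConfig(),
                           spec = regressorSpec(),
                           trainConfig = regTrainConfig()) {
  if (!length(trainImages)) stop("empty training set")
  stopifnot(inherits(trainConfig, "RegTrainConfig"))
  m <- 2^spec$encoderBlocks
  prepare <- function(img) {
    d <- dim(pixels(img))
    tgt <- buildTargetMap(annotations(img), d[1:2], targetConfig)
    list(x = padToMultiple(toNet(pixels(img)), m)$x,
         t = padToMultiple(mapValues(tgt), m)$x, H = d[1], W = d[2])
  }
  tr <- lapply(trainImages, prepare)
  va <- lapply(valImages, prepare)

  R <- buildRegressor(spec, deriveSeed(trainConfig$seed, 1))
  state <- adamInit(regGetParams(R))
  nTr <- length(tr)
  evalLoss <- function(set) {
    mean(vapply(set, function(s) {
      y <- regForward(R, s$x)$y
      mean((cropTo(y, s$H, s$W) - cropTo(s$t, s$H, s$W))^2)
    }, numeric(1)))
  }
  log <- data.frame(epoch = seq_len(trainConfig$epochs), train = NA_real_,
                    val = NA_real_)
  best <- list(loss = Inf, params = NULL, epoch = 0L)
  for (ep in seq_len(trainConfig$epochs)) {
    ord <- withSeed(deriveSeed(trainConfig$seed, 100 + ep), sample.int(nTr))
    epLoss <- 0
    for (i in ord) {
      s <- tr[[i]]
      f <- regForward(R, s$x)
      diff <- f$y - s$t
      epLoss <- epLoss + mean(diff^2)
      b <- regBackward(R, f$caches, 2 * diff / length(diff))
      upd <- adamUpdate2(R, b$grads, state, trainConfig$lr)
      R <- upd$R; state <- upd$state
    }
    log$train[ep] <- epLoss / nTr
    log$val[ep] <- if (length(va)) evalLoss(va) else log$train[ep]
    if (log$val[ep] < best$loss) {
      best <- list(loss = log$val[ep], params = regGetParams(R), epoch = ep)
    }
  }
  if (!is.null(best$params)) R <- regSetParams(R, best$params)
  structure(list(model = R, log = log, bestEpoch = best$epoch,
                 spec = spec, seed = trainConfig$seed),
            class = "ki67RegressorFit")
}

# Adam over the regressor's grouped parameter tree.
adamUpdate2 <- function(R, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  p <- regGetParams(R)
  r <- adamTree(p, grads, state$m, state$v, lr, beta1, beta2, eps, state$t)
  state$m <- r$m; state$v <- r$v
  list(R = regSetParams(R, r$p), state = state)
}
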