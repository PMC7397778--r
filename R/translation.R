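# Cycle-consistent adversarial translation between the two stain domains.
# Images live in [0,1]; networks operate in [-1,1] (tanh output head).

toNet <- function(img01) img01 * 2 - 1
fromNet <- function(x) clamp01((x + 1) / 2)

#' Build a translation generator
#'
#' Residual fully convolutional generator: 7x7 reflection-padded stem,
#' `downsamplings` stride-2 convolutions, `blocks` residual blocks,
#' mirrored nearest-neighbor upsamplings and a 7x7 tanh head. Maps an
#' H x W x 3 image to an H x W x 3 image (inputs are reflection-padded to
#' a multiple of the total downsampling factor and cropped back).
#'
#' @param spec a [generatorSpec()].
#' @param seed integer seed for weight initialization.
#' @return a generator model (list with class `ki67Generator`); apply it
#'   with [applyGenerator()].
#' @export
buildGenerator <- function(spec, seed) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  w <- spec$baseWidth
  net <- withSeed(seed, {
    layers <- list(lyConv(3, w, 7, 1, 3, "reflect"), lyINorm(w),
                   lyAct("relu"))
    wd <- w
    for (d in seq_len(spec$downsamplings)) {
      layers <- c(layers, list(lyConv(wd, wd * 2, 3, 2, 1, "zero"),
                               lyINorm(wd * 2), lyAct("relu")))
      wd <- wd * 2
    }
    for (b in seq_len(spec$blocks))
      layers <- c(layers, list(lyRes(wd)))
    for (d in seq_len(spec$downsamplings)) {
      layers <- c(layers, list(lyUp(2), lyConv(wd, wd %/% 2, 3, 1, 1, "zero"),
                               lyINorm(wd %/% 2), lyAct("relu")))
      wd <- wd %/% 2
    }
    c(layers, list(lyConv(wd, 3, 7, 1, 3, "reflect"), lyAct("tanh")))
  })
  structure(list(net = net, spec = spec, seed = seed),
            class = "ki67Generator")
}

# Forward pass in network space with caches (input already in [-1,1] and
# dims divisible by the downsampling factor).
genForwardRaw <- function(G, x) netForward(G$net, x)

#' Apply a generator to an image
#'
#' @param G a `ki67Generator` from [buildGenerator()].
#' @param img01 H x W x 3 array in [0, 1].
#' @return translated H x W x 3 array in [0, 1], same dims as the input.
#' @export
applyGenerator <- function(G, img01) {
  stopifnot(inherits(G, "ki67Generator"))
  m <- 2^G$spec$downsamplings
  p <- padToMultiple(toNet(img01), m)
  y <- netForward(G$net, p$x)$y
  fromNet(cropTo(y, p$H, p$W))
}

#' Build a PatchGAN discriminator
#'
#' Stack of unpadded strided 4x4 convolutions with leaky-ReLU (instance
#' norm from the second layer on) ending in a 1-channel score map: one
#' real/fake score per receptive patch rather than a single scalar.
#'
#' @param spec a [discriminatorSpec()].
#' @param seed integer seed for weight initialization.
#' @return a discriminator model (list with class `ki67Discriminator`);
#'   apply it with [applyDiscriminator()].
#' @export
buildDiscriminator <- function(spec, seed) {
  stopifnot(inherits(spec, "DiscriminatorSpec"))
  L <- length(spec$kernels)
  w <- spec$baseWidth
  net <- withSeed(seed, {
    layers <- list()
    cin <- 3
    for (i in seq_len(L - 1)) {
      cout <- min(w * 2^(i - 1), w * 8)
      layers <- c(layers, list(lyConv(cin, cout, spec$kernels[i],
                                      spec$strides[i], 0, "zero")))
      if (i > 1) layers <- c(layers, list(lyINorm(cout)))
      layers <- c(layers, list(lyAct("lrelu")))
      cin <- cout
    }
    c(layers, list(lyConv(cin, 1, spec$kernels[L], spec$strides[L], 0,
                          "zero")))
  })
  structure(list(net = net, spec = spec, seed = seed),
            class = "ki67Discriminator")
}

#' Apply a discriminator to an image
#'
#' @param D a `ki67Discriminator`.
#' @param img01 H x W x 3 array in [0, 1]; must be large enough for the
#'   unpadded convolution stack.
#' @return matrix of patch scores (spatial map, possibly 1 x 1).
#' @export
applyDiscriminator <- function(D, img01) {
  stopifnot(inherits(D, "ki67Discriminator"))
  y <- netForward(D$net, toNet(img01))$y
  matrix(y, dim(y)[1], dim(y)[2])
}

# Forward pass through a flat (conv/inorm/act) net collecting the
# instance-norm statistics, and a replay that reuses frozen statistics, so
# receptive-field probing measures the convolutional path only (the
# normalization statistics couple all pixels globally and are not part of
# the architectural receptive field).
discForwardStats <- function(net, x) {
  stats <- vector("list", length(net))
  for (i in seq_along(net)) {
    l <- net[[i]]
    if (l$type == "inorm") {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      mu <- colMeans(xm)
      invs <- 1 / sqrt(colMeans(xm * xm) - mu * mu + l$eps)
      stats[[i]] <- list(mu = mu, invs = invs)
      xm <- sweep(sweep(xm, 2, mu, "-"), 2, invs * l$gamma, "*")
      x <- array(sweep(xm, 2, l$beta, "+"), d)
    } else x <- layerForward(l, x)$y
  }
  list(y = x, stats = stats)
}

discForwardFrozen <- function(net, x, stats) {
  for (i in seq_along(net)) {
    l <- net[[i]]
    if (l$type == "inorm") {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      xm <- sweep(sweep(xm, 2, stats[[i]]$mu, "-"), 2,
                  stats[[i]]$invs * l$gamma, "*")
      x <- array(sweep(xm, 2, l$beta, "+"), d)
    } else x <- layerForward(l, x)$y
  }
  x
}

#' Measure a discriminator's receptive field by perturbation probing
#'
#' Feeds a fixed input, then perturbs single pixels along a row and a
#' column and records which ones change a chosen output unit. Instance-norm
#' statistics are frozen at their base-input values during the probe, so
#' the measurement characterizes the convolutional path (normalization
#' statistics couple all pixels globally and are not part of the
#' architectural receptive field). The extent of the responding span is
#' the empirical receptive field; for the reference configuration it is
#' exactly 70 pixels on each axis.
#'
#' @param D a `ki67Discriminator`.
#' @param inputSize side length of the square probe image.
#' @param unit length-2 output-unit index (row, col), 1-based; defaults to
#'   a unit whose field lies inside the probe image.
#' @return named vector with elements `rows` and `cols` (pixel extents).
#' @export
measureReceptiveField <- function(D, inputSize = 80, unit = c(2, 2)) {
  x <- withSeed(271, array(stats::runif(inputSize^2 * 3), c(inputSize, inputSize, 3)))
  fs <- discForwardStats(D$net, toNet(x))
  base <- fs$y
  stopifnot(all(unit <= dim(base)[1:2]))
  # probe lines chosen inside the target unit's field
  line <- inputSize %/% 2
  probe <- function(axis) {
    hits <- logical(inputSize)
    for (i in seq_len(inputSize)) {
      xp <- x
      if (axis == 1) xp[i, line, ] <- 1 - xp[i, line, ] else
        xp[line, i, ] <- 1 - xp[line, i, ]
      out <- discForwardFrozen(D$net, toNet(xp), fs$stats)
      hits[i] <- abs(out[unit[1], unit[2], 1] - base[unit[1], unit[2], 1]) >
        1e-9
    }
    if (!any(hits)) return(0L)
    diff(range(which(hits))) + 1L
  }
  c(rows = probe(1), cols = probe(2))
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between an image and its reconstruction after
#' a round trip through both generators; zero iff the images are
#' identical.
#' @param x,xRec arrays of identical shape.
#' @return nonnegative scalar.
#' @export
cycleLoss <- function(x, xRec) {
  if (!identical(dim(x), dim(xRec))) stop("shape mismatch")
  mean(abs(x - xRec))
}

#' Least-squares adversarial losses
#'
#' Least-squares GAN objective on patch score maps: the discriminator is
#' driven towards 1 on real and 0 on fake patches, the generator towards
#' fake patches scoring 1.
#' @param real,fake discriminator score maps (any shape).
#' @return list with `lossD` = (mean((real-1)^2) + mean(fake^2)) / 2 and
#'   `lossG` = mean((fake-1)^2).
#' @export
adversarialLosses <- function(real, fake) {
  if (!all(is.finite(real)) || !all(is.finite(fake)))
    stop("non-finite discriminator scores")
  list(lossD = (mean((real - 1)^2) + mean(fake^2)) / 2,
       lossG = mean((fake - 1)^2))
}

#' Train a cycle-consistent GAN on an unpaired domain pair
#'
#' Alternates Adam updates of the two generators (adversarial + cycle
#' objectives) and the two discriminators (least-squares real/fake
#' objective), one source and one target image per iteration in a fixed
#' seeded order. Annotations are ignored: translation is unpaired and
#' unsupervised. Deterministic given the config seed.
#'
#' @param source,target non-empty lists of [AnnotatedImage-class] objects.
#' @param config a [ganTrainConfig()].
#' @param genSpec a [generatorSpec()] shared by both generators.
#' @param discSpec a [discriminatorSpec()] shared by both discriminators.
#' @return list of class `ki67CycleGAN` with elements `Gst`, `Gts`
#'   (generators), `Ds`, `Dt` (discriminators) and `trace`, a per-iteration
#'   data.frame of the generator, cycle and discriminator losses.
#' @export
trainCycleGAN <- function(source, target, config, genSpec, discSpec) {
  stopifnot(inherits(config, "GanTrainConfig"))
  if (!length(source) || !length(target))
    stop("source and target sets must be non-empty")
  m <- 2^genSpec$downsamplings
  prep <- function(img) padToMultiple(toNet(pixels(img)), m)$x
  xs <- lapply(source, prep)
  xt <- lapply(target, prep)

  Gst <- buildGenerator(genSpec, deriveSeed(config$seed, 1))
  Gts <- buildGenerator(genSpec, deriveSeed(config$seed, 2))
  Ds <- buildDiscriminator(discSpec, deriveSeed(config$seed, 3))
  Dt <- buildDiscriminator(discSpec, deriveSeed(config$seed, 4))

  stG <- list(Gst = adamInit(netGetParams(Gst$net)),
              Gts = adamInit(netGetParams(Gts$net)),
              Ds = adamInit(netGetParams(Ds$net)),
              Dt = adamInit(netGetParams(Dt$net)))
  lam <- config$lambdaCycle
  lamId <- if (is.null(config$lambdaIdentity)) 0 else config$lambdaIdentity
  n <- config$iterations
  trace <- data.frame(iteration = seq_len(n), lossG = NA_real_,
                      cycle = NA_real_, lossDs = NA_real_, lossDt = NA_real_)
  order_s <- withSeed(config$seed, sample.int(length(xs)))
  order_t <- withSeed(config$seed + 1L, sample.int(length(xt)))

  for (it in seq_len(n)) {
    x_s <- xs[[order_s[(it - 1) %% length(xs) + 1]]]
    x_t <- xt[[order_t[(it - 1) %% length(xt) + 1]]]

    # ---- generator update -------------------------------------------------
    fSt1 <- netForward(Gst$net, x_s)          # fake target
    fTs1 <- netForward(Gts$net, fSt1$y)       # source reconstruction
    fTs2 <- netForward(Gts$net, x_t)          # fake source
    fSt2 <- netForward(Gst$net, fTs2$y)       # target reconstruction
    dT <- netForward(Dt$net, fSt1$y)
    dS <- netForward(Ds$net, fTs2$y)

    adv_t <- mean((dT$y - 1)^2)
    adv_s <- mean((dS$y - 1)^2)
    cycS <- mean(abs(fTs1$y - x_s))
    cycT <- mean(abs(fSt2$y - x_t))

    # adversarial gradients through the (frozen) discriminators
    dAdvT <- netBackward(Dt$net, dT$caches, 2 * (dT$y - 1) / length(dT$y))$dx
    dAdvS <- netBackward(Ds$net, dS$caches, 2 * (dS$y - 1) / length(dS$y))$dx
    # cycle gradients (L1)
    dRecS <- lam * sign(fTs1$y - x_s) / length(x_s)
    dRecT <- lam * sign(fSt2$y - x_t) / length(x_t)

    bTs1 <- netBackward(Gts$net, fTs1$caches, dRecS)
    bSt1 <- netBackward(Gst$net, fSt1$caches, dAdvT + bTs1$dx)
    bSt2 <- netBackward(Gst$net, fSt2$caches, dRecT)
    bTs2 <- netBackward(Gts$net, fTs2$caches, dAdvS + bSt2$dx)

    gGst <- treeAdd(bSt1$grads, bSt2$grads)
    gGts <- treeAdd(bTs1$grads, bTs2$grads)

    # identity-mapping term: each generator applied to its own output
    # domain should change nothing
    if (lamId > 0) {
      iSt <- netForward(Gst$net, x_t)
      iTs <- netForward(Gts$net, x_s)
      gGst <- treeAdd(gGst, netBackward(
        Gst$net, iSt$caches,
        lamId * sign(iSt$y - x_t) / length(x_t))$grads)
      gGts <- treeAdd(gGts, netBackward(
        Gts$net, iTs$caches,
        lamId * sign(iTs$y - x_s) / length(x_s))$grads)
    }
    up <- adamUpdate(Gst$net, gGst, stG$Gst, config$lr, config$beta1)
    Gst$net <- up$net; stG$Gst <- up$state
    up <- adamUpdate(Gts$net, gGts, stG$Gts, config$lr, config$beta1)
    Gts$net <- up$net; stG$Gts <- up$state

    # ---- discriminator updates (generator outputs detached) ---------------
    fakeT <- fSt1$y
    fakeS <- fTs2$y
    updD <- function(D, st, real, fake) {
      fr <- netForward(D$net, real)
      ff <- netForward(D$net, fake)
      loss <- (mean((fr$y - 1)^2) + mean(ff$y^2)) / 2
      br <- netBackward(D$net, fr$caches, (fr$y - 1) / length(fr$y))
      bf <- netBackward(D$net, ff$caches, ff$y / length(ff$y))
      up <- adamUpdate(D$net, treeAdd(br$grads, bf$grads), st, config$lr,
                       config$beta1)
      list(net = up$net, state = up$state, loss = loss)
    }
    rT <- updD(Dt, stG$Dt, x_t, fakeT)
    Dt$net <- rT$net; stG$Dt <- rT$state
    rS <- updD(Ds, stG$Ds, x_s, fakeS)
    Ds$net <- rS$net; stG$Ds <- rS$state

    trace$lossG[it] <- adv_t + adv_s
    trace$cycle[it] <- cycS + cycT
    trace$lossDs[it] <- rS$loss
    trace$lossDt[it] <- rT$loss
  }
  structure(list(Gst = Gst, Gts = Gts, Ds = Ds, Dt = Dt, trace = trace,
                 config = config),
            class = "ki67CycleGAN")
}

#' Translate a set of annotated images
#'
#' Replaces each image's pixels by the generator output (clipped to
#' [0, 1]); annotations and case ids are copied through unchanged, which
#' is what makes source labels reusable on converted images.
#'
#' @param G a `ki67Generator`, or any function mapping an H x W x 3 array
#'   to an array of the same shape (e.g. `identity`).
#' @param images list of [AnnotatedImage-class] objects.
#' @return list of translated [AnnotatedImage-class] objects.
#' @export
translateImages <- function(G, images) {
  fun <- if (inherits(G, "ki67Generator")) function(p) applyGenerator(G, p)
         else G
  lapply(images, function(img) {
    out <- clamp01(fun(pixels(img)))
    if (!identical(dim(out), dim(pixels(img)))) stop("shape mismatch")
    AnnotatedImage(out, annotations(img), caseId(img))
  })
}

#' Save / load a trained model with a JSON sidecar
#'
#' Serializes a generator, discriminator, regressor or full CycleGAN to an
#' RDS file plus a `<path>.json` sidecar recording the spec and seed for
#' provenance.
#' @param model the model object.
#' @param path file path for the checkpoint.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  side <- list(class = class(model)[1],
               spec = model$spec, seed = model$seed,
               saved = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
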