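#' Layout parameters for the synthetic nucleus generator
#'
#' Controls how many nuclei of each class are placed on a tile, how large
#' they are and how strongly they cluster. Defaults define the synthetic
#' study conditions used throughout the package's desk-scale experiments:
#' 64 x 64 tiles with an INT-heavy class mixture echoing the class
#' imbalance typical of Ki-67 NET images.
#'
#' @param height,width tile dimensions in pixels (>= 64).
#' @param nIpt,nInt,nNt per-class nucleus counts (>= 0).
#' @param radiusRange min/max nucleus semi-major axis in pixels (min >= 2).
#' @param minSeparation minimum pairwise center distance in pixels (> 0).
#' @param clustering in [0, 1]; 0 places nuclei uniformly, larger values
#'   concentrate them around a few cluster centers, as nuclei do in tissue.
#' @return validated parameter list of class `LayoutParams`.
#' @export
layoutParams <- function(height = 64, width = 64, nIpt = 4, nInt = 8, nNt = 4,
                         radiusRange = c(3, 5), minSeparation = 9,
                         clustering = 0.5) {
  stopifnot(height >= 64, width >= 64, nIpt >= 0, nInt >= 0, nNt >= 0,
            length(radiusRange) == 2, radiusRange[1] >= 2,
            radiusRange[2] >= radiusRange[1], minSeparation > 0,
            clustering >= 0)
  total <- nIpt + nInt + nNt
  # crude packing feasibility: each nucleus claims a disc of diameter
  # minSeparation; refuse layouts that cannot fit even at 70% packing
  if (total * pi * (minSeparation / 2)^2 > 0.7 * height * width)
    stop("requested nucleus counts are infeasible for the image area")
  structure(list(height = as.integer(height), width = as.integer(width),
                 nIpt = as.integer(nIpt), nInt = as.integer(nInt),
                 nNt = as.integer(nNt), radiusRange = radiusRange,
                 minSeparation = minSeparation, clustering = clustering),
            class = "LayoutParams")
}

#' Style parameters for the synthetic renderer
#'
#' Defines the appearance of one imaging "institution": background color,
#' per-class nucleus colors, per-nucleus color jitter, background texture
#' amplitude, and a global hue/contrast transform that implements the
#' systematic appearance shift between domains.
#'
#' Class colors follow the IHC visual convention: IPT nuclei are
#' DAB-brown, INT nuclei hematoxylin-blue, NT nuclei a paler blue-gray.
#'
#' @param background length-3 RGB background mean in [0, 1].
#' @param classColors 3 x 3 matrix, rows (IPT, INT, NT), RGB in [0, 1].
#' @param jitter per-nucleus color jitter sd (>= 0).
#' @param noise background texture amplitude (>= 0).
#' @param gamma length-3 per-channel exponents (> 0) applied to the
#'   rendered intensities; stain/scanner response is multiplicative in
#'   optical density, so appearance shifts between institutions are
#'   power-law rather than additive in transmitted intensity.
#' @param hueShift length-3 additive RGB shift applied globally.
#' @param contrast global contrast multiplier (> 0) about mid-gray.
#' @return validated parameter list of class `StyleParams`.
#' @export
styleParams <- function(background = c(0.88, 0.83, 0.86),
                        classColors = rbind(IPT = c(0.45, 0.26, 0.13),
                                            INT = c(0.25, 0.30, 0.58),
                                            NT  = c(0.52, 0.58, 0.66)),
                        jitter = 0.02, noise = 0.02,
                        gamma = c(1, 1, 1),
                        hueShift = c(0, 0, 0), contrast = 1) {
  classColors <- as.matrix(classColors)
  stopifnot(length(background) == 3, all(background >= 0 & background <= 1),
            all(dim(classColors) == c(3, 3)),
            all(classColors >= 0 & classColors <= 1),
            jitter >= 0, noise >= 0, length(gamma) == 3, all(gamma > 0),
            length(hueShift) == 3, contrast > 0)
  rownames(classColors) <- nucleusClasses()
  structure(list(background = background, classColors = classColors,
                 jitter = jitter, noise = noise, gamma = gamma,
                 hueShift = hueShift, contrast = contrast),
            class = "StyleParams")
}

#' Preset style for the shifted "target" institution
#'
#' The default source style pushed through a per-channel gamma transform
#' (strong red absorption, boosted blue), a mild additive hue shift
#' towards cooler tones, reduced contrast and stronger texture -- a
#' stand-in for the stain/scanner appearance shift between institutions.
#' The transform is deliberately nonlinear in intensity, as real stain
#' variation is, so it cannot be undone by any global affine color map.
#' @return a `StyleParams` object.
#' @export
targetStyleParams <- function() {
  styleParams(gamma = c(1.8, 1.25, 0.6), hueShift = c(-0.06, 0, 0.06),
              contrast = 0.9, noise = 0.05)
}

#' Gaussian proximity target-map configuration
#'
#' Supervision for the regressor: each annotation contributes a Gaussian
#' bump of height `peak` and scale `sigma`, truncated at `radius`, on its
#' class channel; overlapping bumps combine by pixelwise maximum so each
#' nucleus keeps exactly one strict maximum.
#'
#' @param sigma Gaussian scale in pixels (> 0).
#' @param radius truncation radius in pixels (> 0); default 3 sigma.
#' @param peak bump height (> 0).
#' @param decay decay shape identifier; only "gaussian" is implemented.
#' @return list of class `TargetMapConfig`.
#' @export
targetMapConfig <- function(sigma = 4, radius = 3 * sigma, peak = 1,
                            decay = "gaussian") {
  stopifnot(sigma > 0, radius > 0, peak > 0, decay == "gaussian")
  structure(list(sigma = sigma, radius = radius, peak = peak, decay = decay),
            class = "TargetMapConfig")
}

#' Post-processing configuration (eta suppression + local maxima)
#'
#' @param eta suppression fraction in [0, 1]: responses below
#'   `eta * max(map)` are zeroed before peak finding.
#' @param neighborhood local-maximum neighborhood radius in pixels (>= 1).
#' @param minSeparation minimum distance between reported peaks (>= 1).
#' @param perChannel if TRUE, suppression runs on each class channel
#'   before the channels are merged; the default suppresses the merged map.
#' @return list of class `PostprocessConfig`.
#' @export
postprocessConfig <- function(eta = 0.5, neighborhood = 3, minSeparation = 5,
                              perChannel = FALSE) {
  stopifnot(eta >= 0, eta <= 1, neighborhood >= 1, minSeparation >= 1)
  structure(list(eta = eta, neighborhood = as.integer(neighborhood),
                 minSeparation = minSeparation, perChannel = perChannel),
            class = "PostprocessConfig")
}

#' Evaluation configuration
#'
#' @param radius gold-standard radius r in pixels: a detection can match an
#'   annotation only within the circle of radius r around it.
#' @param etaGrid strictly increasing suppression thresholds in [0, 1] used
#'   to trace the precision-recall curve.
#' @param radii radii for the gold-standard-radius sensitivity analysis.
#' @return list of class `EvalConfig`.
#' @export
evalConfig <- function(radius = 16, etaGrid = seq(0, 1, length.out = 101),
                       radii = c(8, 12, 16)) {
  stopifnot(radius > 0, all(etaGrid >= 0 & etaGrid <= 1),
            all(diff(etaGrid) > 0), all(radii > 0))
  structure(list(radius = radius, etaGrid = etaGrid, radii = radii),
            class = "EvalConfig")
}

#' Case-level split specification
#'
#' Cases are split into training (50%) and test (50%) halves, with 20% of
#' the training cases (at least one) held out for validation; two-fold
#' cross-validation swaps the roles of the halves.
#'
#' @param trainFraction fraction of cases assigned to training.
#' @param valFraction fraction of training cases used for validation.
#' @param folds number of cross-validation folds (2 swaps halves).
#' @param seed integer seed controlling the random case permutation.
#' @return list of class `SplitSpec`.
#' @export
splitSpec <- function(trainFraction = 0.5, valFraction = 0.2, folds = 2,
                      seed = 1) {
  stopifnot(trainFraction > 0, trainFraction < 1, valFraction > 0,
            valFraction < 1, folds %in% c(1, 2))
  structure(list(trainFraction = trainFraction, valFraction = valFraction,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "SplitSpec")
}

#' Training-regime specification
#'
#' @param regime one of "baseline_source_only" (regressor trained on raw
#'   source images), "adapted" (trained on GAN-converted source images),
#'   "mixed" (converted source plus k annotated target training images), or
#'   "target_supervised" (trained on annotated target images; the ceiling).
#' @param sourceFraction fraction of source training cases used.
#' @param k number of real annotated target training images mixed in
#'   (mixed regime only; k = 0 reduces mixed to adapted).
#' @param includeOriginalSource if TRUE (default) the adapted/mixed
#'   regimes train on original source images alongside the converted
#'   ones, which regularizes the regressor against residual conversion
#'   artifacts.
#' @return list of class `RegimeSpec`.
#' @export
regimeSpec <- function(regime = c("baseline_source_only", "adapted", "mixed",
                                  "target_supervised"),
                       sourceFraction = 1, k = 0,
                       includeOriginalSource = TRUE) {
  regime <- match.arg(regime)
  stopifnot(sourceFraction > 0, sourceFraction <= 1, k >= 0)
  if (k > 0 && regime != "mixed")
    stop("k > 0 requires the mixed regime")
  structure(list(regime = regime, sourceFraction = sourceFraction,
                 k = as.integer(k),
                 includeOriginalSource = includeOriginalSource),
            class = "RegimeSpec")
}

#' Translation generator architecture
#'
#' The canonical residual translation generator: 7x7 stem, two stride-2
#' downsamplings, `blocks` residual blocks, mirrored nearest-neighbor
#' upsamplings and a 7x7 tanh output head, with instance normalization and
#' reflection padding throughout. The reference configuration uses 9
#' residual blocks; tests run reduced widths and block counts.
#'
#' @param blocks number of residual blocks (>= 1).
#' @param baseWidth stem channel width.
#' @param downsamplings number of stride-2 stages (each doubles the width).
#' @return list of class `GeneratorSpec`.
#' @export
generatorSpec <- function(blocks = 9, baseWidth = 64, downsamplings = 2) {
  stopifnot(blocks >= 1, baseWidth >= 1, downsamplings >= 0)
  structure(list(blocks = as.integer(blocks),
                 baseWidth = as.integer(baseWidth),
                 downsamplings = as.integer(downsamplings)),
            class = "GeneratorSpec")
}

#' PatchGAN discriminator architecture
#'
#' A stack of unpadded 4x4 convolutions producing a spatial map of
#' real/fake scores, one per receptive patch. The reference configuration
#' (5 layers, strides 2,2,2,1,1) has a 70 x 70 pixel receptive field per
#' output unit; see [receptiveField()].
#'
#' @param baseWidth first-layer channel width (doubles per layer, capped at
#'   8x).
#' @param kernels integer kernel size per convolution (the last produces
#'   the 1-channel score map).
#' @param strides integer stride per convolution.
#' @return list of class `DiscriminatorSpec`.
#' @export
discriminatorSpec <- function(baseWidth = 64, kernels = c(4, 4, 4, 4, 4),
                              strides = c(2, 2, 2, 1, 1)) {
  stopifnot(length(kernels) == length(strides), all(kernels >= 1),
            all(strides >= 1), baseWidth >= 1)
  structure(list(baseWidth = as.integer(baseWidth),
                 kernels = as.integer(kernels),
                 strides = as.integer(strides)),
            class = "DiscriminatorSpec")
}

#' Analytic receptive field of a discriminator spec
#'
#' Composes kernel sizes and strides back-to-front: one output unit of the
#' reference configuration sees exactly 70 x 70 input pixels.
#' @param spec a `DiscriminatorSpec`.
#' @return receptive field side length in pixels.
#' @export
receptiveField <- function(spec) {
  stopifnot(inherits(spec, "DiscriminatorSpec"))
  rf <- 1
  for (i in rev(seq_along(spec$kernels)))
    rf <- (rf - 1) * spec$strides[i] + spec$kernels[i]
  rf
}

#' GAN training configuration
#'
#' @param lambdaCycle cycle-consistency weight (> 0); conventional value 10.
#' @param lambdaIdentity identity-mapping weight (>= 0; 0 disables). The
#'   identity term |G_st(x_t) - x_t| anchors the color mapping so the
#'   generator does not drift hue where no change is needed; the
#'   conventional weight is half the cycle weight.
#' @param lr Adam learning rate.
#' @param beta1 Adam first-moment decay (0.5 is the family default).
#' @param iterations number of generator/discriminator update steps (>= 1).
#' @param seed integer seed; training is deterministic given it.
#' @param lossForm adversarial loss identifier; "lsgan" (least squares) is
#'   the implemented form.
#' @return list of class `GanTrainConfig`.
#' @export
ganTrainConfig <- function(lambdaCycle = 10, lambdaIdentity = lambdaCycle / 2,
                           lr = 2e-4, beta1 = 0.5,
                           iterations = 200, seed = 1, lossForm = "lsgan") {
  stopifnot(lambdaCycle > 0, lambdaIdentity >= 0, lr > 0, iterations >= 1,
            lossForm == "lsgan")
  structure(list(lambdaCycle = lambdaCycle, lambdaIdentity = lambdaIdentity,
                 lr = lr, beta1 = beta1,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), lossForm = lossForm),
            class = "GanTrainConfig")
}

#' Proximity-map regressor architecture
#'
#' Residual encoder-decoder with long-range skip connections and
#' multi-level fusion: `encoderBlocks` stride-2 residual stages, a mirrored
#' decoder, decoder features from every level resized to full resolution
#' and concatenated, then a 2-convolution head with a rectified 3-channel
#' output (one channel per nucleus class).
#'
#' @param encoderBlocks,decoderBlocks residual stages (>= 1; equal when
#'   skip connections are on). The reference configuration uses 4 and 4.
#' @param baseWidth stem channel width.
#' @param skip enable long-range encoder-decoder skip connections.
#' @param fusion enable multi-level feature fusion before the head.
#' @param norm "none" (default, as in the original U-Net family),
#'   "interior" (instance norm everywhere except the stem) or "instance"
#'   (everywhere). Full instance normalization makes the network exactly
#'   invariant to global affine color shifts -- appropriate for the
#'   translation generators, but it would mask exactly the appearance
#'   sensitivity that motivates domain adaptation of the regressor.
#' @return list of class `RegressorSpec`.
#' @export
regressorSpec <- function(encoderBlocks = 4, decoderBlocks = 4,
                          baseWidth = 16, skip = TRUE, fusion = TRUE,
                          norm = c("none", "interior", "instance")) {
  norm <- match.arg(norm)
  stopifnot(encoderBlocks >= 1, decoderBlocks >= 1, baseWidth >= 1)
  if (skip && encoderBlocks != decoderBlocks)
    stop("skip connections require equal encoder and decoder block counts")
  structure(list(encoderBlocks = as.integer(encoderBlocks),
                 decoderBlocks = as.integer(decoderBlocks),
                 baseWidth = as.integer(baseWidth), skip = skip,
                 fusion = fusion, norm = norm),
            class = "RegressorSpec")
}

#' Regressor training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs training epochs (>= 1); the weights with the best
#'   validation loss are returned.
#' @param seed integer seed for initialization and data order.
#' @return list of class `RegTrainConfig`.
#' @export
regTrainConfig <- function(lr = 3e-3, epochs = 20, seed = 1) {
  stopifnot(lr > 0, epochs >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "RegTrainConfig")
}
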