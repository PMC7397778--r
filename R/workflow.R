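# Orchestration of the experimental designs: case-level splitting with
# two-fold cross-validation, the four training regimes, and the
# source-fraction / target-count sweeps. A label-hygiene audit log records
# every annotation access so tests can prove target test labels are never
# read before evaluation.

#' Split cases into train / validation / test folds
#'
#' Permutes the case ids under the spec seed, assigns `trainFraction` of
#' them to training and the rest to test, and carves `valFraction` of the
#' training cases (at least one) out as validation. With two folds the
#' train and test halves swap roles in fold 2.
#'
#' @param caseIds character vector of at least 5 distinct case ids.
#' @param spec a [splitSpec()].
#' @return list of folds, each a list with `train`, `validation` and
#'   `test` character vectors (disjoint, exhaustive).
#' @export
splitCases <- function(caseIds, spec = splitSpec()) {
  stopifnot(inherits(spec, "SplitSpec"))
  caseIds <- unique(caseIds)
  n <- length(caseIds)
  if (n < 5) stop("need at least 5 cases for a case-level split")
  perm <- withSeed(spec$seed, sample(caseIds))
  nTrain <- round(n * spec$trainFraction)
  half1 <- perm[seq_len(nTrain)]
  half2 <- perm[-seq_len(nTrain)]
  carve <- function(trainAll) {
    nVal <- max(1L, round(spec$valFraction * length(trainAll)))
    list(train = trainAll[seq_len(length(trainAll) - nVal)],
         validation = trainAll[length(trainAll) - nVal + seq_len(nVal)])
  }
  f1 <- carve(half1)
  folds <- list(list(train = f1$train, validation = f1$validation,
                     test = half2))
  if (spec$folds == 2) {
    f2 <- carve(half2)
    folds[[2]] <- list(train = f2$train, validation = f2$validation,
                       test = half1)
  }
  folds
}

subsetByCase <- function(images, cases) {
  Filter(function(img) caseId(img) %in% cases, images)
}

stripAnnotations <- function(images) {
  lapply(images, function(img)
    AnnotatedImage(pixels(img), emptyAnnotations(), caseId(img)))
}

auditEntry <- function(stage, cases, labelsUsed) {
  data.frame(stage = stage, cases = paste(sort(cases), collapse = ","),
             labelsUsed = labelsUsed, stringsAsFactors = FALSE)
}

# Default desk-scale option bundle for regime experiments. Every component
# is overridable; the defaults are sized for 64 x 64 synthetic tiles.
#' Options bundle for [runRegime()]
#'
#' Collects the network, training and evaluation configurations used by
#' the regime runner, with desk-scale defaults sized for 64 x 64
#' synthetic tiles.
#' @param genSpec,discSpec,ganConfig translation-stage configuration.
#' @param regSpec,targetConfig,regTrainConfig regression-stage
#'   configuration.
#' @param postConfig,evalCfg post-processing / evaluation configuration.
#' @param split a [splitSpec()] (its seed is replaced by the run seed).
#' @return list of class `RegimeOptions`.
#' @export
regimeOptions <- function(genSpec = generatorSpec(blocks = 2, baseWidth = 8),
                          discSpec = discriminatorSpec(baseWidth = 16,
                                                       kernels = c(4, 4, 4),
                                                       strides = c(2, 2, 1)),
                          ganConfig = ganTrainConfig(iterations = 150),
                          regSpec = regressorSpec(encoderBlocks = 3,
                                                  decoderBlocks = 3,
                                                  baseWidth = 8),
                          targetConfig = targetMapConfig(),
                          regTrainConfig = Ki67Adapt::regTrainConfig(
                            epochs = 24),
                          postConfig = postprocessConfig(),
                          evalCfg = evalConfig(
                            radius = 8,
                            etaGrid = seq(0, 1, length.out = 21)),
                          split = splitSpec()) {
  structure(list(genSpec = genSpec, discSpec = discSpec,
                 ganConfig = ganConfig, regSpec = regSpec,
                 targetConfig = targetConfig,
                 regTrainConfig = regTrainConfig, postConfig = postConfig,
                 evalCfg = evalCfg, split = split),
            class = "RegimeOptions")
}

# Fit the translation stage on source-train + (unlabeled) target-train
# images and convert the source training set. Factored out so sweeps can
# reuse one GAN across several regressor fits.
fitTranslation <- function(sourceTrain, targetTrain, opts, seed) {
  cfg <- opts$ganConfig
  cfg$seed <- deriveSeed(seed, 11)
  gan <- trainCycleGAN(sourceTrain, stripAnnotations(targetTrain), cfg,
                       opts$genSpec, opts$discSpec)
  list(gan = gan,
       converted = translateImages(gan$Gst, sourceTrain))
}

#' Run one training regime and evaluate on the target test fold
#'
#' Splits both datasets at the case level (fold 1), trains the regressor
#' according to the regime, predicts proximity maps on the target test
#' images and returns the full [MetricsReport-class]. Target test
#' annotations are touched only at evaluation; the report's meta carries
#' an audit log of every annotation access proving it.
#'
#' Regimes: `baseline_source_only` trains on raw source training images;
#' `adapted` converts them with a CycleGAN fitted to the (unlabeled)
#' target training images first; `mixed` additionally appends `k` real
#' annotated target training images; `target_supervised` trains on the
#' annotated target training images only (the supervised ceiling).
#'
#' @param source,target lists of [AnnotatedImage-class] objects.
#' @param regime a [regimeSpec()].
#' @param opts a [regimeOptions()] bundle.
#' @param seed master integer seed for the run.
#' @return a [MetricsReport-class] with regime, seed and audit metadata.
#' @export
runRegime <- function(source, target, regime, opts = regimeOptions(),
                      seed = 1) {
  stopifnot(inherits(regime, "RegimeSpec"), inherits(opts, "RegimeOptions"))
  spl <- opts$split
  spl$seed <- deriveSeed(seed, 1)
  tFolds <- splitCases(vapply(target, caseId, character(1)), spl)
  spl$seed <- deriveSeed(seed, 2)
  sFolds <- splitCases(vapply(source, caseId, character(1)), spl)

  targetTrain <- subsetByCase(target, tFolds[[1]]$train)
  targetVal <- subsetByCase(target, tFolds[[1]]$validation)
  targetTest <- subsetByCase(target, tFolds[[1]]$test)
  nSrcTrain <- max(1L, round(regime$sourceFraction *
                               length(sFolds[[1]]$train)))
  sourceTrain <- subsetByCase(source, sFolds[[1]]$train[seq_len(nSrcTrain)])
  sourceVal <- subsetByCase(source, sFolds[[1]]$validation)

  audit <- auditEntry("split", vapply(target, caseId, character(1)), FALSE)
  trCfg <- opts$regTrainConfig
  trCfg$seed <- deriveSeed(seed, 21)

  trainSet <- NULL; valSet <- NULL
  if (regime$regime == "baseline_source_only") {
    trainSet <- sourceTrain
    valSet <- sourceVal
    audit <- rbind(audit, auditEntry(
      "train", vapply(sourceTrain, caseId, character(1)), TRUE))
  } else if (regime$regime %in% c("adapted", "mixed")) {
    tf <- fitTranslation(sourceTrain, targetTrain, opts, seed)
    audit <- rbind(audit, auditEntry(
      "gan", c(vapply(sourceTrain, caseId, character(1)),
               vapply(targetTrain, caseId, character(1))), FALSE))
    trainSet <- tf$converted
    if (regime$includeOriginalSource)
      trainSet <- c(trainSet, sourceTrain)
    valSet <- translateImages(tf$gan$Gst, sourceVal)
    audit <- rbind(audit, auditEntry(
      "train", vapply(sourceTrain, caseId, character(1)), TRUE))
    if (regime$regime == "mixed" && regime$k > 0) {
      if (regime$k > length(targetTrain))
        stop("k exceeds the available target training images")
      extra <- targetTrain[seq_len(regime$k)]
      trainSet <- c(trainSet, extra)
      audit <- rbind(audit, auditEntry(
        "train-target", vapply(extra, caseId, character(1)), TRUE))
    }
  } else if (regime$regime == "target_supervised") {
    trainSet <- targetTrain
    valSet <- targetVal
    audit <- rbind(audit, auditEntry(
      "train", vapply(targetTrain, caseId, character(1)), TRUE))
  }

  fit <- trainRegressor(trainSet, valSet, opts$targetConfig, opts$regSpec,
                        trCfg)
  maps <- lapply(targetTest, function(img) predictMap(fit$model, img))
  annList <- lapply(targetTest, annotations)
  audit <- rbind(audit, auditEntry(
    "evaluate", vapply(targetTest, caseId, character(1)), TRUE))
  # label hygiene: no test case may appear in a pre-evaluation stage that
  # used labels
  trainStages <- audit[audit$labelsUsed & audit$stage != "evaluate", ]
  trainCases <- unlist(strsplit(trainStages$cases, ","))
  if (any(vapply(targetTest, caseId, character(1)) %in% trainCases))
    stop("label hygiene violation: target test labels used in training")
  metricsReport(maps, annList, opts$evalCfg, opts$postConfig,
                meta = list(regime = regime, seed = seed, audit = audit,
                            folds = list(target = tFolds, source = sFolds),
                            trainLog = fit$log))
}

#' Sweep the fraction of source training data
#'
#' Runs the adapted regime (or mixed, when `k > 0`) at each source
#' fraction for each seed and tabulates detection and weighted
#' classification F1.
#'
#' @param source,target image lists.
#' @param fractions source-fraction values in (0, 1].
#' @param k real target training images mixed in (fixed across fractions).
#' @param opts a [regimeOptions()] bundle.
#' @param seeds integer seeds; one run per (fraction, seed).
#' @return data.frame with fraction, seed, f1Detection, f1Classification.
#' @export
sweepSourceFraction <- function(source, target, fractions, k = 0,
                                opts = regimeOptions(), seeds = 1) {
  if (!length(fractions)) stop("empty fraction list")
  stopifnot(all(fractions > 0 & fractions <= 1))
  rows <- list()
  for (s in seeds) for (f in fractions) {
    reg <- regimeSpec(if (k > 0) "mixed" else "adapted", sourceFraction = f,
                      k = k)
    rep <- runRegime(source, target, reg, opts, s)
    rows[[length(rows) + 1]] <- data.frame(
      fraction = f, seed = s,
      f1Detection = detectionMetrics(rep)$f1,
      f1Classification = weightedMetrics(rep)$f1)
  }
  do.call(rbind, rows)
}

#' Sweep the number of real target training images
#'
#' Fixes the source fraction (default 0.4, the saturation point of the
#' source sweep) and varies the number k of annotated target training
#' images mixed into the converted-source training set; k = 0 reduces to
#' the adapted regime.
#'
#' @param source,target image lists.
#' @param ks nonnegative integers.
#' @param sourceFraction fixed source fraction.
#' @param opts a [regimeOptions()] bundle.
#' @param seeds integer seeds.
#' @return data.frame with k, seed, f1Detection, f1Classification.
#' @export
sweepTargetCount <- function(source, target, ks, sourceFraction = 0.4,
                             opts = regimeOptions(), seeds = 1) {
  stopifnot(all(ks >= 0))
  rows <- list()
  for (s in seeds) for (k in ks) {
    reg <- regimeSpec(if (k > 0) "mixed" else "adapted",
                      sourceFraction = sourceFraction, k = k)
    rep <- runRegime(source, target, reg, opts, s)
    rows[[length(rows) + 1]] <- data.frame(
      k = k, seed = s,
      f1Detection = detectionMetrics(rep)$f1,
      f1Classification = weightedMetrics(rep)$f1)
  }
  do.call(rbind, rows)
}
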