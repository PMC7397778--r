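# The quantitative protocol: gold-standard circular regions, Hungarian
# one-to-one association (cardinality-first, then minimum total distance),
# precision/recall/F1, PR curves with AUC over the eta sweep, weighted
# multi-class aggregation, pixel-grid confusion and radius sensitivity.

BIG_COST <- 1e8

#' Associate detections with annotations by the Hungarian algorithm
#'
#' One-to-one assignment between detections and annotations. Pairs whose
#' Euclidean distance exceeds the gold-standard radius `r` (or whose
#' labels differ, when `classRestricted`) are infeasible; among feasible
#' assignments the match maximizes the number of pairs first and
#' minimizes the total distance second. Matched pairs are TPs, unmatched
#' detections FPs, unmatched annotations FNs.
#'
#' @param detections data.frame with `row`, `col` (and `label` if
#'   class-restricted), e.g. from [detectNuclei()].
#' @param annotations data.frame with `row`, `col`, `label`.
#' @param r gold-standard radius in pixels (> 0).
#' @param classRestricted if TRUE only same-label pairs may match.
#' @return a [MatchResult-class].
#' @export
matchDetections <- function(detections, annotations, r,
                            classRestricted = FALSE) {
  stopifnot(r > 0)
  det <- as.data.frame(detections)
  ann <- as.data.frame(annotations)
  nd <- nrow(det); na <- nrow(ann)
  emptyPairs <- data.frame(detection = integer(0), annotation = integer(0),
                           distance = numeric(0))
  if (nd == 0 || na == 0) {
    return(new("MatchResult", pairs = emptyPairs, fp = seq_len(nd),
               fn = seq_len(na), radius = r))
  }
  dist <- outer(det$row, ann$row, "-")^2 + outer(det$col, ann$col, "-")^2
  dist <- sqrt(dist)
  cost <- dist
  cost[dist > r] <- BIG_COST
  if (classRestricted) {
    labDiff <- outer(det$label, ann$label, "!=")
    cost[labDiff] <- BIG_COST
  }
  if (nd <= na) {
    asg <- cpp_hungarian(cost) + 1L
    pairs <- data.frame(detection = seq_len(nd), annotation = asg,
                        distance = cost[cbind(seq_len(nd), asg)])
  } else {
    asg <- cpp_hungarian(t(cost)) + 1L
    pairs <- data.frame(detection = asg, annotation = seq_len(na),
                        distance = cost[cbind(asg, seq_len(na))])
  }
  ok <- pairs$distance < BIG_COST / 2
  pairs <- pairs[ok, , drop = FALSE]
  rownames(pairs) <- NULL
  new("MatchResult", pairs = pairs,
      fp = setdiff(seq_len(nd), pairs$detection),
      fn = setdiff(seq_len(na), pairs$annotation), radius = r)
}

#' Precision, recall and F1 from counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), with the conventions
#' P = 0 when TP+FP = 0, R = 0 when TP+FN = 0 and F1 = 0 when P+R = 0.
#' @param tp,fp,fn nonnegative counts.
#' @return named vector (precision, recall, f1).
#' @export
prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be nonnegative")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Pixel-grid confusion statistics
#'
#' Treats every pixel of the evaluation grid as a unit: TN is the number
#' of grid pixels that are neither TP, FP nor FN; specificity is
#' TN/(TN+FP) and sensitivity TP/(TP+FN) (0 when undefined).
#' @param tp,fp,fn counts with tp+fp+fn <= prod(grid).
#' @param grid length-2 (H, W) of the evaluation grid.
#' @return list with tn, specificity, sensitivity.
#' @export
pixelConfusion <- function(tp, fp, fn, grid) {
  total <- prod(grid)
  if (tp + fp + fn > total) stop("counts exceed the grid size")
  tn <- total - tp - fp - fn
  list(tn = tn,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# Pooled (micro-average) counts over images at one eta.
pooledCounts <- function(maps, annList, eta, postConfig, r, class = NULL) {
  pc <- postConfig
  pc$eta <- eta
  tp <- fp <- fn <- 0
  for (i in seq_along(maps)) {
    det <- detectNuclei(maps[[i]], pc)
    ann <- as.data.frame(annList[[i]])
    if (!is.null(class)) {
      det <- det[det$label == class, , drop = FALSE]
      ann <- ann[ann$label == class, , drop = FALSE]
    }
    mr <- matchDetections(det, ann, r, classRestricted = !is.null(class))
    ct <- matchCounts(mr)
    tp <- tp + ct["tp"]; fp <- fp + ct["fp"]; fn <- fn + ct["fn"]
  }
  c(tp = unname(tp), fp = unname(fp), fn = unname(fn))
}

# Trapezoidal area under a PR point set: points sorted by recall, curve
# anchored at (recall 0, precision of the lowest-recall point).
prCurveAuc <- function(precision, recall) {
  o <- order(recall, precision)
  r <- c(0, recall[o])
  p <- c(precision[o][1], precision[o])
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Precision-recall curve and AUC over the eta sweep
#'
#' For every suppression threshold eta in the grid, detections are
#' recomputed on every map, pooled over images, and matched to the
#' annotations; the resulting (precision, recall) points are integrated
#' by the trapezoidal rule over recall, with the curve anchored at recall
#' zero at the precision of its lowest-recall point.
#'
#' @param maps list of [OutputMap-class] objects.
#' @param annList per-image list of annotation data.frames.
#' @param config an [evalConfig()] (radius and eta grid).
#' @param mode "detection" (merged-channel matching, any label) or a
#'   single class name for the class-restricted curve.
#' @param postConfig a [postprocessConfig()] providing the peak-finding
#'   parameters.
#' @return list with `curve` (data.frame eta/precision/recall) and `auc`.
#' @export
prAuc <- function(maps, annList, config = evalConfig(), mode = "detection",
                  postConfig = postprocessConfig()) {
  stopifnot(inherits(config, "EvalConfig"), length(maps) == length(annList))
  class <- if (identical(mode, "detection")) NULL else mode
  nAnn <- sum(vapply(annList, function(a) {
    a <- as.data.frame(a)
    if (is.null(class)) nrow(a) else sum(a$label == class)
  }, numeric(1)))
  if (nAnn == 0) stop("no annotations in scope: recall undefined")
  pts <- t(vapply(config$etaGrid, function(eta) {
    ct <- pooledCounts(maps, annList, eta, postConfig, config$radius, class)
    prf(ct["tp"], ct["fp"], ct["fn"])[1:2]
  }, numeric(2)))
  curve <- data.frame(eta = config$etaGrid, precision = pts[, 1],
                      recall = pts[, 2])
  list(curve = curve, auc = prCurveAuc(curve$precision, curve$recall))
}

#' Weight per-class metrics by class frequency
#'
#' The weighted average of per-class precision, recall, F1 and AUC with
#' weights equal to each class's share of the test-set annotations.
#' @param perClass data.frame with one row per class and columns
#'   `precision`, `recall`, `f1`, `auc` (rows in class order IPT, INT, NT).
#' @param classCounts annotation counts per class (same order); at least
#'   one must be positive.
#' @return list with weighted precision, recall, f1, auc.
#' @export
weightedClassificationMetrics <- function(perClass, classCounts) {
  if (any(classCounts < 0) || sum(classCounts) == 0)
    stop("class counts must be nonnegative with a positive sum")
  w <- classCounts / sum(classCounts)
  as.list(vapply(c("precision", "recall", "f1", "auc"),
                 function(m) sum(w * perClass[[m]]), numeric(1)))
}

#' F1 sensitivity to the gold-standard radius
#'
#' Recomputes detection-mode and weighted classification F1 at the
#' default eta for each radius in `config$radii`. For fixed detections a
#' larger radius can only add feasible pairs, so F1 is non-decreasing in
#' the radius.
#'
#' @param maps list of [OutputMap-class] objects.
#' @param annList per-image list of annotation data.frames.
#' @param config an [evalConfig()].
#' @param postConfig a [postprocessConfig()].
#' @return data.frame with columns `radius`, `mode`, `f1`.
#' @export
radiusSensitivity <- function(maps, annList, config = evalConfig(),
                              postConfig = postprocessConfig()) {
  rows <- lapply(config$radii, function(r) {
    det <- pooledCounts(maps, annList, postConfig$eta, postConfig, r)
    f1det <- prf(det["tp"], det["fp"], det["fn"])["f1"]
    counts <- vapply(nucleusClasses(), function(cl)
      sum(vapply(annList, function(a)
        sum(as.data.frame(a)$label == cl), numeric(1))), numeric(1))
    perClass <- do.call(rbind, lapply(nucleusClasses(), function(cl) {
      ct <- pooledCounts(maps, annList, postConfig$eta, postConfig, r, cl)
      m <- prf(ct["tp"], ct["fp"], ct["fn"])
      data.frame(precision = m["precision"], recall = m["recall"],
                 f1 = m["f1"], auc = NA_real_)
    }))
    present <- counts > 0
    f1cls <- if (any(present))
      sum((counts[present] / sum(counts[present])) * perClass$f1[present])
    else 0
    data.frame(radius = r, mode = c("detection", "classification"),
               f1 = c(unname(f1det), f1cls))
  })
  do.call(rbind, rows)
}

#' Full evaluation report for a set of predicted maps
#'
#' Computes pooled detection metrics and per-class classification metrics
#' at the configured eta, PR-AUCs over the eta grid, the weighted
#' classification aggregate, and pixel-grid confusion statistics (the
#' grid is the union of all map pixels).
#'
#' @param maps list of [OutputMap-class] objects.
#' @param annList per-image list of annotation data.frames.
#' @param config an [evalConfig()].
#' @param postConfig a [postprocessConfig()].
#' @param meta optional provenance list carried into the report.
#' @return a [MetricsReport-class].
#' @export
metricsReport <- function(maps, annList, config = evalConfig(),
                          postConfig = postprocessConfig(), meta = list()) {
  stopifnot(length(maps) == length(annList))
  detCt <- pooledCounts(maps, annList, postConfig$eta, postConfig,
                        config$radius)
  detPrf <- prf(detCt["tp"], detCt["fp"], detCt["fn"])
  detAuc <- prAuc(maps, annList, config, "detection", postConfig)$auc
  detection <- list(precision = unname(detPrf["precision"]),
                    recall = unname(detPrf["recall"]),
                    f1 = unname(detPrf["f1"]), auc = detAuc,
                    tp = unname(detCt["tp"]), fp = unname(detCt["fp"]),
                    fn = unname(detCt["fn"]))
  counts <- vapply(nucleusClasses(), function(cl)
    sum(vapply(annList, function(a)
      sum(as.data.frame(a)$label == cl), numeric(1))), numeric(1))
  perClass <- do.call(rbind, lapply(nucleusClasses(), function(cl) {
    ct <- pooledCounts(maps, annList, postConfig$eta, postConfig,
                       config$radius, cl)
    m <- prf(ct["tp"], ct["fp"], ct["fn"])
    auc <- if (counts[cl] > 0)
      prAuc(maps, annList, config, cl, postConfig)$auc else NA_real_
    data.frame(class = cl, precision = unname(m["precision"]),
               recall = unname(m["recall"]), f1 = unname(m["f1"]),
               auc = auc, tp = unname(ct["tp"]), fp = unname(ct["fp"]),
               fn = unname(ct["fn"]), count = unname(counts[cl]))
  }))
  rownames(perClass) <- NULL
  present <- counts > 0
  weighted <- weightedClassificationMetrics(
    perClass[present, , drop = FALSE], counts[present])
  gridPixels <- sum(vapply(maps, function(m) prod(dim(mapValues(m))[1:2]),
                           numeric(1)))
  pc <- pixelConfusion(detection$tp, detection$fp, detection$fn,
                       c(gridPixels, 1))
  pixel <- list(tp = detection$tp, fp = detection$fp, fn = detection$fn,
                tn = pc$tn, specificity = pc$specificity,
                sensitivity = pc$sensitivity, grid = gridPixels)
  new("MetricsReport", detection = detection, perClass = perClass,
      weighted = weighted, pixel = pixel, classCounts = counts, meta = meta)
}
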