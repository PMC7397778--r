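#' AnnotatedImage: an RGB tile with point ground truth
#'
#' Container for one histology image tile: an H x W x 3 pixel array with
#' intensities in [0, 1], a table of per-nucleus point annotations
#' (0-based pixel coordinates plus a class label), and a case identifier
#' used for case-level data splitting.
#'
#' @slot pixels numeric H x W x 3 array, values in [0, 1], H and W >= 64.
#' @slot annotations data.frame with columns `row`, `col` (0-based integer
#'   pixel indices from top/left) and `label` (one of IPT, INT, NT).
#' @slot caseId non-empty character scalar.
#' @export
setClass("AnnotatedImage",
  representation(pixels = "array", annotations = "data.frame",
                 caseId = "character"))

setValidity("AnnotatedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3) return("pixels must be an H x W x 3 array")
  if (d[1] < 64 || d[2] < 64) return("image must be at least 64 x 64")
  if (anyNA(object@pixels)) return("pixels contain NA")
  if (min(object@pixels) < 0 || max(object@pixels) > 1)
    return("pixel intensities must lie in [0, 1]")
  a <- object@annotations
  if (!all(c("row", "col", "label") %in% names(a)))
    return("annotations need columns row, col, label")
  if (nrow(a)) {
    if (!all(a$label %in% nucleusClasses())) return("unknown class label")
    if (any(a$row < 0 | a$row >= d[1] | a$col < 0 | a$col >= d[2]))
      return("annotation outside image bounds")
  }
  if (length(object@caseId) != 1 || !nzchar(object@caseId))
    return("caseId must be a non-empty string")
  TRUE
})

#' Construct an AnnotatedImage
#'
#' @param pixels H x W x 3 numeric array in [0, 1].
#' @param annotations data.frame with 0-based `row`, `col` and `label`
#'   columns; defaults to an empty table.
#' @param caseId case identifier string.
#' @return An [AnnotatedImage-class] object.
#' @export
AnnotatedImage <- function(pixels, annotations = emptyAnnotations(),
                           caseId = "case") {
  new("AnnotatedImage", pixels = pixels,
      annotations = as.data.frame(annotations), caseId = caseId)
}

#' @describeIn AnnotatedImage-class pixel array accessor
#' @param object,x an AnnotatedImage
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("pixels", "AnnotatedImage", function(x) x@pixels)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("annotations", "AnnotatedImage", function(x) x@annotations)

#' @rdname AnnotatedImage-class
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname AnnotatedImage-class
#' @export
setMethod("caseId", "AnnotatedImage", function(x) x@caseId)

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@pixels)
  tab <- table(factor(object@annotations$label, levels = nucleusClasses()))
  cat(sprintf("AnnotatedImage %s: %d x %d, %d nuclei (IPT %d, INT %d, NT %d)\n",
              object@caseId, d[1], d[2], nrow(object@annotations),
              tab["IPT"], tab["INT"], tab["NT"]))
})

#' OutputMap: per-class proximity response map
#'
#' The regressor's prediction y-hat: a nonnegative H x W x 3 array whose
#' channels, in fixed order (IPT, INT, NT), carry a radially decaying bump
#' around each predicted nucleus center of that class.
#'
#' @slot values nonnegative numeric H x W x 3 array.
#' @export
setClass("OutputMap", representation(values = "array"))

setValidity("OutputMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 3 || d[3] != 3) return("values must be H x W x 3")
  if (anyNA(object@values)) return("values contain NA")
  if (min(object@values) < 0) return("proximity responses must be nonnegative")
  TRUE
})

#' Construct an OutputMap
#' @param values nonnegative H x W x 3 numeric array, channels (IPT, INT, NT).
#' @return An [OutputMap-class] object.
#' @export
OutputMap <- function(values) {
  dimnames(values) <- list(NULL, NULL, nucleusClasses())
  new("OutputMap", values = values)
}

#' @rdname OutputMap-class
#' @param x an OutputMap
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname OutputMap-class
#' @export
setMethod("mapValues", "OutputMap", function(x) x@values)

setMethod("show", "OutputMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("OutputMap %d x %d x 3, max responses IPT %.3f INT %.3f NT %.3f\n",
              d[1], d[2], max(object@values[, , 1]),
              max(object@values[, , 2]), max(object@values[, , 3])))
})

#' MatchResult: Hungarian association of detections with annotations
#'
#' One-to-one minimum-distance assignment between predicted nucleus centers
#' and gold-standard annotations within radius-r gold-standard areas.
#' Matched pairs are true positives; unmatched detections are false
#' positives; unmatched annotations are false negatives.
#'
#' @slot pairs data.frame with columns `detection`, `annotation` (1-based
#'   indices into the input tables) and `distance` (Euclidean pixels).
#' @slot fp integer indices of unmatched detections.
#' @slot fn integer indices of unmatched annotations.
#' @slot radius the gold-standard radius r used.
#' @export
setClass("MatchResult",
  representation(pairs = "data.frame", fp = "integer", fn = "integer",
                 radius = "numeric"))

setValidity("MatchResult", function(object) {
  p <- object@pairs
  if (!all(c("detection", "annotation", "distance") %in% names(p)))
    return("pairs needs columns detection, annotation, distance")
  if (anyDuplicated(p$detection) || anyDuplicated(p$annotation))
    return("assignment is not one-to-one")
  if (any(p$detection %in% object@fp) || any(p$annotation %in% object@fn))
    return("matched index also listed as FP/FN")
  if (nrow(p) && any(p$distance > object@radius + 1e-9))
    return("matched distance exceeds the gold-standard radius")
  TRUE
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult (r = %g px): %d TP, %d FP, %d FN\n",
              object@radius, nrow(object@pairs), length(object@fp),
              length(object@fn)))
})

#' @rdname MatchResult-class
#' @param x a MatchResult
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
#' @rdname MatchResult-class
#' @export
setMethod("matchedPairs", "MatchResult", function(x) x@pairs)

#' Counts (TP, FP, FN) from a MatchResult
#' @param x a MatchResult
#' @return named integer vector with elements tp, fp, fn.
#' @export
matchCounts <- function(x) {
  stopifnot(is(x, "MatchResult"))
  c(tp = nrow(x@pairs), fp = length(x@fp), fn = length(x@fn))
}

#' MetricsReport: the full quantitative evaluation of one experiment
#'
#' Pooled (micro-averaged) detection metrics, per-class classification
#' metrics, their weighted aggregate (weights = class frequencies among the
#' test annotations), and pixel-grid confusion statistics.
#'
#' @slot detection list with precision, recall, f1, auc, tp, fp, fn.
#' @slot perClass data.frame, one row per class, with the same metrics.
#' @slot weighted list with weighted precision, recall, f1, auc.
#' @slot pixel list with tp, fp, fn, tn, specificity, sensitivity, grid.
#' @slot classCounts named numeric vector of annotation counts per class.
#' @slot meta free-form provenance list (regime, seeds, configs, audit log).
#' @export
setClass("MetricsReport",
  representation(detection = "list", perClass = "data.frame",
                 weighted = "list", pixel = "list",
                 classCounts = "numeric", meta = "list"))

setValidity("MetricsReport", function(object) {
  rates <- unlist(object@detection[c("precision", "recall", "f1")])
  if (length(rates) && (any(rates < -1e-12) || any(rates > 1 + 1e-12)))
    return("detection rates outside [0, 1]")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  d <- object@detection
  w <- object@weighted
  cat(sprintf("MetricsReport\n  detection:      P %.4f R %.4f F1 %.4f AUC %.4f\n",
              d$precision, d$recall, d$f1, d$auc))
  cat(sprintf("  classification: P %.4f R %.4f F1 %.4f AUC %.4f (weighted)\n",
              w$precision, w$recall, w$f1, w$auc))
  cat(sprintf("  pixel grid:     TP %d FP %d FN %d TN %d\n",
              object@pixel$tp, object@pixel$fp, object@pixel$fn,
              object@pixel$tn))
})

#' @rdname MetricsReport-class
#' @param x a MetricsReport
#' @export
setGeneric("detectionMetrics", function(x) standardGeneric("detectionMetrics"))
#' @rdname MetricsReport-class
#' @export
setMethod("detectionMetrics", "MetricsReport", function(x) x@detection)

#' @rdname MetricsReport-class
#' @export
setGeneric("classMetrics", function(x) standardGeneric("classMetrics"))
#' @rdname MetricsReport-class
#' @export
setMethod("classMetrics", "MetricsReport", function(x) x@perClass)

#' @rdname MetricsReport-class
#' @export
setGeneric("weightedMetrics", function(x) standardGeneric("weightedMetrics"))
#' @rdname MetricsReport-class
#' @export
setMethod("weightedMetrics", "MetricsReport", function(x) x@weighted)

#' @rdname MetricsReport-class
#' @export
setGeneric("pixelMetrics", function(x) standardGeneric("pixelMetrics"))
#' @rdname MetricsReport-class
#' @export
setMethod("pixelMetrics", "MetricsReport", function(x) x@pixel)

#' @rdname MetricsReport-class
#' @export
setGeneric("reportMeta", function(x) standardGeneric("reportMeta"))
#' @rdname MetricsReport-class
#' @export
setMethod("reportMeta", "MetricsReport", function(x) x@meta)
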