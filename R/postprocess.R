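# From proximity maps to discrete detections: eta-fraction suppression,
# plateau-aware local maxima with minimum separation, channel merging and
# channel-argmax classification.

#' Suppress sub-threshold responses
#'
#' Sets every value below `eta * max(channel)` to zero and leaves the rest
#' unchanged. An all-zero channel is returned unchanged; `eta = 0` is a
#' no-op for nonnegative maps.
#'
#' @param channel numeric H x W matrix (nonnegative).
#' @param eta fraction of the channel maximum in [0, 1].
#' @return the suppressed matrix.
#' @export
suppressMap <- function(channel, eta) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  m <- max(channel)
  if (m == 0) return(channel)
  channel[channel < eta * m] <- 0
  channel
}

#' Merge the three class channels
#'
#' Pixelwise maximum across the (IPT, INT, NT) channels: the single map on
#' which detection-mode peak finding runs.
#' @param map an [OutputMap-class] or H x W x 3 array.
#' @return H x W matrix.
#' @export
mergeChannels <- function(map) {
  v <- if (is(map, "OutputMap")) mapValues(map) else map
  stopifnot(length(dim(v)) == 3, dim(v)[3] == 3)
  matrix(pmax(v[, , 1], v[, , 2], v[, , 3]), dim(v)[1], dim(v)[2])
}

# Label connected components (8-connectivity) among the TRUE cells of a
# logical matrix; returns an integer matrix of component ids (0 = FALSE).
labelComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      qi <- (q - 1L) %% H + 1L
      qj <- (q - 1L) %/% H + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- qi + di; jj <- qj + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        pp <- (jj - 1L) * H + ii
        if (mask[pp] && lab[pp] == 0L) {
          lab[pp] <- cur
          queue <- c(queue, pp)
        }
      }
    }
  }
  lab
}

#' Find local maxima of a response map
#'
#' A pixel is a candidate peak if its value is positive and not exceeded
#' by any neighbor within the circular `neighborhood` radius. Plateaus
#' (connected candidates of equal value) are collapsed to their
#' lexicographically smallest pixel. Candidates are then greedily accepted
#' in order of descending value (ties broken by row, then column) subject
#' to a minimum pairwise separation.
#'
#' @param map nonnegative H x W matrix.
#' @param config a [postprocessConfig()] (uses `neighborhood` and
#'   `minSeparation`).
#' @return data.frame with 0-based `row`, `col` and `value`, sorted by
#'   descending value.
#' @export
localMaxima <- function(map, config = postprocessConfig()) {
  stopifnot(inherits(config, "PostprocessConfig"))
  if (min(map) < 0) stop("map must be nonnegative")
  mf <- cpp_maxfilter(map, config$neighborhood)
  cand <- map > 0 & map >= mf
  if (!any(cand)) {
    return(data.frame(row = integer(0), col = integer(0),
                      value = numeric(0)))
  }
  # collapse plateaus: among touching candidates of equal value keep the
  # lexicographic smallest representative
  lab <- labelComponents(cand)
  reps <- data.frame(row = integer(0), col = integer(0), value = numeric(0))
  for (k in seq_len(max(lab))) {
    cells <- which(lab == k)
    vals <- map[cells]
    for (v in unique(vals)) {
      sub <- cells[vals == v]
      ri <- (sub - 1L) %% nrow(map)
      ci <- (sub - 1L) %/% nrow(map)
      o <- order(ri, ci)[1]
      reps <- rbind(reps, data.frame(row = ri[o], col = ci[o], value = v))
    }
  }
  reps <- reps[order(-reps$value, reps$row, reps$col), , drop = FALSE]
  keptR <- numeric(0); keptC <- numeric(0); keep <- logical(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    if (!length(keptR) ||
        min(sqrt((keptR - reps$row[i])^2 + (keptC - reps$col[i])^2)) >=
          config$minSeparation) {
      keep[i] <- TRUE
      keptR <- c(keptR, reps$row[i]); keptC <- c(keptC, reps$col[i])
    }
  }
  out <- reps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a map location by channel argmax
#'
#' Returns the label of the channel with the largest response at the
#' given pixel; exact ties resolve by the fixed channel priority
#' IPT > INT > NT.
#' @param map an [OutputMap-class] or H x W x 3 array.
#' @param point length-2 (row, col), 0-based.
#' @return one of "IPT", "INT", "NT".
#' @export
classifyPoint <- function(map, point) {
  v <- if (is(map, "OutputMap")) mapValues(map) else map
  r <- point[1] + 1L; cc <- point[2] + 1L
  if (r < 1 || r > dim(v)[1] || cc < 1 || cc > dim(v)[2])
    stop("point out of bounds")
  nucleusClasses()[which.max(v[r, cc, ])]
}

#' Detect and classify nuclei from a proximity map
#'
#' Detection-mode pipeline: merge the three channels (pixelwise maximum),
#' suppress responses below `eta * max`, find local maxima as nucleus
#' centers, and label each center by channel argmax of the original map.
#' Classification mode yields the identical centers with labels attached
#' (labels are attached in both modes). With `perChannel = TRUE` in the
#' config, suppression runs per channel before merging instead.
#'
#' @param map an [OutputMap-class] or H x W x 3 array.
#' @param config a [postprocessConfig()].
#' @param mode "detection" or "classification".
#' @return data.frame with 0-based `row`, `col`, `label` and `score`
#'   (merged-map value at the peak), sorted by descending score.
#' @export
detectNuclei <- function(map, config = postprocessConfig(),
                         mode = c("detection", "classification")) {
  mode <- match.arg(mode)
  v <- if (is(map, "OutputMap")) mapValues(map) else map
  if (config$perChannel) {
    sup <- array(0, dim(v))
    for (ch in 1:3) sup[, , ch] <- suppressMap(v[, , ch], config$eta)
    merged <- mergeChannels(sup)
  } else {
    merged <- suppressMap(mergeChannels(v), config$eta)
  }
  peaks <- localMaxima(merged, config)
  if (!nrow(peaks)) return(emptyDetections())
  labels <- vapply(seq_len(nrow(peaks)), function(i)
    classifyPoint(v, c(peaks$row[i], peaks$col[i])), character(1))
  data.frame(row = peaks$row, col = peaks$col, label = labels,
             score = peaks$value, stringsAsFactors = FALSE)
}
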