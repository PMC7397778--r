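# Shared fixtures and independent oracles used across the suite.

tinyLayout <- function(...) layoutParams(...)

# a deterministic random nonnegative map
randomMap <- function(H = 24, W = 24, seed = 1, sparsity = 0.7) {
  set.seed(seed)
  m <- matrix(stats::runif(H * W), H, W)
  m[m < sparsity] <- 0
  m
}

randomOutputMap <- function(H = 24, W = 24, seed = 1) {
  set.seed(seed)
  OutputMap(array(stats::runif(H * W * 3)^3, c(H, W, 3)))
}

# Direct O(H W k^2) re-implementation of the local-maxima definition:
# candidate = positive and not exceeded within the circular radius;
# touching equal-valued candidates collapse to the lexicographically
# smallest pixel; greedy min-separation selection by descending value.
bruteLocalMaxima <- function(map, radius, minSep) {
  H <- nrow(map); W <- ncol(map)
  cand <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- map[i, j]
    if (v <= 0) next
    ok <- TRUE
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di * di + dj * dj > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      if (map[ii, jj] > v) ok <- FALSE
    }
    cand[i, j] <- ok
  }
  # collapse equal-valued 8-connected candidate plateaus
  seen <- matrix(FALSE, H, W)
  reps <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!cand[i, j] || seen[i, j]) next
    comp <- list(c(i, j)); seen[i, j] <- TRUE; q <- list(c(i, j))
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        if (cand[ii, jj] && !seen[ii, jj] &&
            map[ii, jj] == map[p[1], p[2]]) {
          seen[ii, jj] <- TRUE
          comp[[length(comp) + 1]] <- c(ii, jj)
          q[[length(q) + 1]] <- c(ii, jj)
        }
      }
    }
    cm <- do.call(rbind, comp)
    cm <- cm[order(cm[, 1], cm[, 2]), , drop = FALSE]
    reps <- rbind(reps, c(cm[1, ], map[cm[1, 1], cm[1, 2]]))
  }
  if (is.null(reps))
    return(data.frame(row = integer(0), col = integer(0),
                      value = numeric(0)))
  reps <- reps[order(-reps[, 3], reps[, 1], reps[, 2]), , drop = FALSE]
  keep <- rep(FALSE, nrow(reps)); kr <- kc <- numeric(0)
  for (i in seq_len(nrow(reps))) {
    if (!length(kr) ||
        min(sqrt((kr - reps[i, 1])^2 + (kc - reps[i, 2])^2)) >= minSep) {
      keep[i] <- TRUE; kr <- c(kr, reps[i, 1]); kc <- c(kc, reps[i, 2])
    }
  }
  out <- reps[keep, , drop = FALSE]
  data.frame(row = out[, 1] - 1L, col = out[, 2] - 1L, value = out[, 3])
}

# Exhaustive matching oracle: enumerates every injective assignment of
# detections to annotations within radius r, maximizing cardinality then
# minimizing total distance.
bruteMatch <- function(det, ann, r) {
  nd <- nrow(det); na <- nrow(ann)
  best <- list(card = -1L, dist = Inf)
  rec <- function(i, used, card, dist) {
    if (i > nd) {
      if (card > best$card ||
          (card == best$card && dist < best$dist - 1e-12))
        best <<- list(card = card, dist = dist)
      return(invisible())
    }
    rec(i + 1L, used, card, dist)
    for (j in seq_len(na)) {
      if (used[j]) next
      d <- sqrt((det$row[i] - ann$row[j])^2 + (det$col[i] - ann$col[j])^2)
      if (d <= r) {
        used[j] <- TRUE
        rec(i + 1L, used, card + 1L, dist + d)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, na), 0L, 0)
  best
}

randomInstance <- function(seed, maxN = 6, span = 30) {
  set.seed(seed)
  nd <- sample(0:maxN, 1); na <- sample(0:maxN, 1)
  list(det = data.frame(row = runif(nd, 0, span), col = runif(nd, 0, span),
                        label = sample(nucleusClasses(), nd, TRUE)),
       ann = data.frame(row = runif(na, 0, span), col = runif(na, 0, span),
                        label = sample(nucleusClasses(), na, TRUE)))
}

# small rendered image sets reused by training smoke tests
renderSet <- function(n, style = styleParams(), dims = c(64, 64),
                      seedOff = 0, params = layoutParams()) {
  lapply(seq_len(n), function(i) {
    lay <- sampleLayout(params, seedOff + i)
    renderImage(lay, style, dims, seedOff + 1000 + i,
                caseId = sprintf("F%s%02d", seedOff, i),
                radiusRange = params$radiusRange)
  })
}
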