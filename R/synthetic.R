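#' Sample a nucleus layout
#'
#' Places the requested numbers of IPT, INT and NT nucleus centers on the
#' tile by rejection sampling: candidate positions are drawn either around
#' a small set of cluster centers (with probability `clustering`) or
#' uniformly, and accepted only if they keep at least `minSeparation`
#' pixels from every previously accepted center. The result is a pure
#' function of (params, seed).
#'
#' @param params a [layoutParams()] object.
#' @param seed integer seed.
#' @return data.frame with columns `row`, `col` (0-based integer pixel
#'   coordinates) and `label`, one row per nucleus.
#' @export
sampleLayout <- function(params, seed) {
  stopifnot(inherits(params, "LayoutParams"))
  total <- params$nIpt + params$nInt + params$nNt
  if (total == 0) return(emptyAnnotations())
  withSeed(seed, {
    H <- params$height; W <- params$width
    margin <- 2
    nClust <- max(1L, round(total / 6))
    centers <- cbind(stats::runif(nClust, margin, H - 1 - margin),
                     stats::runif(nClust, margin, W - 1 - margin))
    clustSd <- min(H, W) / 6
    rows <- numeric(0); cols <- numeric(0)
    budget <- 1000 * total
    attempts <- 0
    while (length(rows) < total && attempts < budget) {
      attempts <- attempts + 1
      if (stats::runif(1) < params$clustering) {
        ci <- sample.int(nClust, 1)
        r <- stats::rnorm(1, centers[ci, 1], clustSd)
        cc <- stats::rnorm(1, centers[ci, 2], clustSd)
      } else {
        r <- stats::runif(1, margin, H - 1 - margin)
        cc <- stats::runif(1, margin, W - 1 - margin)
      }
      r <- round(r); cc <- round(cc)
      if (r < margin || r > H - 1 - margin || cc < margin ||
          cc > W - 1 - margin) next
      if (length(rows) &&
          min(sqrt((rows - r)^2 + (cols - cc)^2)) < params$minSeparation)
        next
      rows <- c(rows, r); cols <- c(cols, cc)
    }
    if (length(rows) < total)
      stop("could not place all nuclei within the attempt budget; ",
           "layout is too dense")
    labels <- sample(c(rep("IPT", params$nIpt), rep("INT", params$nInt),
                       rep("NT", params$nNt)))
    data.frame(row = as.integer(rows), col = as.integer(cols),
               label = labels, stringsAsFactors = FALSE)
  })
}

# Smooth low-frequency noise field (coarse grid, nearest upsampled, then
# box-blurred) used as background texture.
textureField <- function(H, W, amplitude) {
  if (amplitude == 0) return(matrix(0, H, W))
  g <- 8
  coarse <- matrix(stats::rnorm(ceiling(H / g) * ceiling(W / g), 0, amplitude),
                   ceiling(H / g), ceiling(W / g))
  f <- coarse[rep(seq_len(nrow(coarse)), each = g)[seq_len(H)],
              rep(seq_len(ncol(coarse)), each = g)[seq_len(W)], drop = FALSE]
  for (i in 1:2) {
    f <- (f +
          rbind(f[1, , drop = FALSE], f[-H, , drop = FALSE]) +
          rbind(f[-1, , drop = FALSE], f[H, , drop = FALSE])) / 3
    f <- (f +
          cbind(f[, 1, drop = FALSE], f[, -W, drop = FALSE]) +
          cbind(f[, -1, drop = FALSE], f[, W, drop = FALSE])) / 3
  }
  f
}

#' Render a synthetic Ki-67-like tile
#'
#' Draws each nucleus as a filled ellipse in its class color (plus
#' per-nucleus jitter) over a textured background, then applies the
#' style's global hue/contrast transform. NT nuclei are rendered smaller
#' and more elongated than tumor nuclei, mirroring stromal/lymphocyte
#' morphology. Deterministic given the seed; the layout is attached to the
#' returned image unchanged.
#'
#' @param layout annotation data.frame as returned by [sampleLayout()].
#' @param style a [styleParams()] object.
#' @param dims length-2 integer (H, W).
#' @param seed integer seed.
#' @param caseId case identifier for the returned image.
#' @param radiusRange min/max nucleus semi-major axis in pixels.
#' @return an [AnnotatedImage-class].
#' @export
renderImage <- function(layout, style, dims, seed, caseId = "case",
                        radiusRange = c(3, 5)) {
  stopifnot(inherits(style, "StyleParams"), length(dims) == 2)
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  layout <- as.data.frame(layout)
  if (nrow(layout)) {
    checkLabels(layout$label)
    if (any(layout$row < 0 | layout$row >= H | layout$col < 0 |
            layout$col >= W))
      stop("layout contains out-of-bounds annotations")
  }
  pix <- withSeed(seed, {
    img <- array(0, c(H, W, 3))
    tex <- textureField(H, W, style$noise)
    for (ch in 1:3)
      img[, , ch] <- style$background[ch] + tex +
        stats::rnorm(H * W, 0, style$noise / 2)
    for (i in seq_len(nrow(layout))) {
      lab <- layout$label[i]
      a <- stats::runif(1, radiusRange[1], radiusRange[2])
      if (lab == "NT") {
        # nontumor nuclei: smaller and elongated (stromal morphology)
        a <- max(2, 0.75 * a)
        b <- a * stats::runif(1, 0.45, 0.65)
      } else {
        b <- a * stats::runif(1, 0.7, 0.95)
      }
      theta <- stats::runif(1, 0, pi)
      colr <- clamp01(style$classColors[lab, ] +
                        stats::rnorm(3, 0, style$jitter))
      rc <- layout$row[i] + 1L
      cc <- layout$col[i] + 1L
      ext <- ceiling(a)
      r0 <- max(1L, rc - ext); r1 <- min(H, rc + ext)
      c0 <- max(1L, cc - ext); c1 <- min(W, cc + ext)
      dr <- matrix((r0:r1) - rc, r1 - r0 + 1, c1 - c0 + 1)
      dc <- matrix((c0:c1) - cc, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
      u <- dr * cos(theta) + dc * sin(theta)
      v <- -dr * sin(theta) + dc * cos(theta)
      mask <- (u / a)^2 + (v / b)^2 <= 1
      for (ch in 1:3) {
        sub <- img[r0:r1, c0:c1, ch]
        sub[mask] <- colr[ch]
        img[r0:r1, c0:c1, ch] <- sub
      }
    }
    # global appearance transform: this is the institutional domain shift
    # (per-channel gamma first, then contrast about mid-gray, then shift)
    for (ch in 1:3) {
      v <- pmin(1, pmax(0, img[, , ch]))^style$gamma[ch]
      img[, , ch] <- (v - 0.5) * style$contrast + 0.5 + style$hueShift[ch]
    }
    img
  })
  AnnotatedImage(clamp01(pix), layout, caseId)
}

#' Generate paired source/target synthetic datasets
#'
#' Draws `nSource` + `nTarget` tiles from the same layout distribution but
#' with the two styles, giving a controlled two-institution domain pair
#' with exact point ground truth on both sides (the workflow, not the
#' generator, decides whether target labels may be used). The two styles
#' must differ in at least one field, otherwise there is no domain shift
#' to adapt.
#'
#' @param layout a [layoutParams()] object (shared by both domains).
#' @param styleSource,styleTarget [styleParams()] objects.
#' @param nSource,nTarget image counts.
#' @param seed integer seed; every image derives its own sub-seed.
#' @return list with elements `source` and `target`, each a list of
#'   [AnnotatedImage-class] objects with distinct case ids.
#' @export
makeDomainDatasets <- function(layout, styleSource, styleTarget,
                               nSource, nTarget, seed) {
  stopifnot(inherits(layout, "LayoutParams"), nSource >= 1, nTarget >= 1)
  if (identical(unclass(styleSource), unclass(styleTarget)))
    stop("source and target styles are identical: no domain shift to adapt")
  dims <- c(layout$height, layout$width)
  gen <- function(n, style, prefix, off) {
    lapply(seq_len(n), function(i) {
      lay <- sampleLayout(layout, deriveSeed(seed, off + i))
      renderImage(lay, style, dims, deriveSeed(seed, off + 5000 + i),
                  caseId = sprintf("%s%03d", prefix, i),
                  radiusRange = layout$radiusRange)
    })
  }
  list(source = gen(nSource, styleSource, "S", 0),
       target = gen(nTarget, styleTarget, "T", 20000))
}

#' Nearest-centroid domain classifier accuracy on mean image color
#'
#' Fits one RGB centroid per domain from the mean pixel colors of the two
#' image sets and reports the resubstitution accuracy of nearest-centroid
#' domain assignment. With a material style shift this is near 1; after a
#' successful translation of the source set it should drop towards chance
#' (0.5), which is how the adaptation experiments measure that the domain
#' gap has closed.
#'
#' @param imagesA,imagesB lists of [AnnotatedImage-class] objects.
#' @return accuracy in [0, 1].
#' @export
domainColorAccuracy <- function(imagesA, imagesB) {
  meanColor <- function(img) apply(pixels(img), 3, mean)
  ma <- t(vapply(imagesA, meanColor, numeric(3)))
  mb <- t(vapply(imagesB, meanColor, numeric(3)))
  ca <- colMeans(ma); cb <- colMeans(mb)
  dist2 <- function(m, ctr) rowSums(sweep(m, 2, ctr)^2)
  correct <- c(dist2(ma, ca) <= dist2(ma, cb),
               dist2(mb, cb) < dist2(mb, ca))
  mean(correct)
}
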