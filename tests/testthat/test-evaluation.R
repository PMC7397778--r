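test_that("Hungarian matching is one-to-one within the gold radius", {
  ann <- data.frame(row = c(5, 20, 40), col = c(5, 20, 40),
                    label = c("IPT", "INT", "NT"))
  det <- cbind(ann, score = 1)
  mr <- matchDetections(det, ann, 8)
  expect_equal(unname(matchCounts(mr)), c(3L, 0L, 0L))
  expect_equal(matchedPairs(mr)$distance, rep(0, 3))

  # one detection equidistant from two annotations: one TP, one FN
  det1 <- data.frame(row = 10, col = 15, label = "IPT", score = 1)
  ann2 <- data.frame(row = c(10, 10), col = c(10, 20),
                     label = c("IPT", "IPT"))
  expect_equal(unname(matchCounts(matchDetections(det1, ann2, 8))),
               c(1L, 0L, 1L))

  # class restriction forbids cross-label pairs
  detX <- data.frame(row = 10, col = 10, label = "INT", score = 1)
  annX <- data.frame(row = 10, col = 10, label = "IPT")
  expect_equal(unname(matchCounts(matchDetections(detX, annX, 8,
                                                  classRestricted = TRUE))),
               c(0L, 1L, 1L))
  expect_equal(unname(matchCounts(matchDetections(detX, annX, 8))),
               c(1L, 0L, 0L))

  expect_equal(unname(matchCounts(matchDetections(emptyDetections(),
                                                  ann, 8))),
               c(0L, 0L, 3L))
})

test_that("matching equals the exhaustive assignment oracle", {
  for (s in 1:60) {
    inst <- randomInstance(s)
    mr <- matchDetections(inst$det, inst$ann, r = 12)
    want <- bruteMatch(inst$det, inst$ann, 12)
    expect_equal(nrow(matchedPairs(mr)), want$card, label = paste("seed", s))
    if (want$card > 0)
      expect_equal(sum(matchedPairs(mr)$distance), want$dist,
                   tolerance = 1e-9)
    ct <- matchCounts(mr)
    expect_equal(unname(ct["tp"] + ct["fn"]), nrow(inst$ann))
    expect_equal(unname(ct["tp"] + ct["fp"]), nrow(inst$det))
  }
})

test_that("precision/recall/F1 follow the printed formulas", {
  m <- prf(374, 30, 155)
  expect_equal(unname(m), c(374 / 404, 374 / 529,
                            2 * (374 / 404) * (374 / 529) /
                              (374 / 404 + 374 / 529)))
  expect_equal(unname(prf(0, 0, 0)), c(0, 0, 0))
  expect_equal(unname(prf(10, 0, 0)), c(1, 1, 1))
  expect_error(prf(-1, 0, 0), "nonnegative")
  # harmonic-mean identity on random counts
  for (s in 1:20) {
    set.seed(s)
    ct <- sample(0:50, 3, replace = TRUE)
    m <- prf(ct[1], ct[2], ct[3])
    if (m["precision"] + m["recall"] > 0)
      expect_equal(unname(m["f1"]),
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]), tolerance = 1e-12)
  }
})

test_that("pixel confusion conserves the evaluation grid", {
  expect_equal(pixelConfusion(374, 30, 155, c(596, 596))$tn, 354657)
  expect_equal(pixelConfusion(8, 3, 3, c(596, 596))$tn, 355202)
  expect_equal(pixelConfusion(199, 35, 98, c(596, 596))$tn, 354884)
  expect_equal(pixelConfusion(110, 49, 111, c(596, 596))$tn, 354946)
  pc <- pixelConfusion(0, 0, 0, c(10, 10))
  expect_equal(pc$tn, 100)
  expect_equal(pc$specificity, 1)
  expect_equal(pc$sensitivity, 0)
  expect_error(pixelConfusion(90, 20, 0, c(10, 10)), "grid")
})

test_that("PR curve integration follows the documented convention", {
  # two points {(P=1, R=0.5), (P=0.5, R=1)}: anchor at (R=0, P=1), then
  # trapezoids 0.5*1 + 0.5*(0.75)
  expect_equal(Ki67Adapt:::prCurveAuc(c(1, 0.5), c(0.5, 1)), 0.875)
  expect_equal(Ki67Adapt:::prCurveAuc(c(0.8), c(1)), 0.8)
})

test_that("PR-AUC over the eta sweep behaves at the extremes", {
  lp <- layoutParams(height = 96, width = 96, nIpt = 2, nInt = 3, nNt = 2,
                     minSeparation = 26)
  lays <- lapply(1:3, function(s) sampleLayout(lp, s))
  maps <- lapply(lays, buildTargetMap, dims = c(96, 96))
  cfg <- evalConfig(radius = 8, etaGrid = seq(0, 1, by = 0.1))
  perfect <- prAuc(maps, lays, cfg, "detection")
  expect_true(all(perfect$curve$precision == 1))
  expect_gte(perfect$auc, 0.99)
  zero <- prAuc(lapply(1:3, function(i) OutputMap(array(0, c(96, 96, 3)))),
                lays, cfg, "detection")
  expect_equal(zero$auc, 0)
  expect_error(prAuc(maps, lapply(1:3, function(i) emptyAnnotations()),
                     cfg), "recall")
  # per-class curve for a present class
  cl <- prAuc(maps, lays, cfg, "INT")
  expect_gte(cl$auc, 0.99)
})

test_that("weighted aggregation uses test-set class frequencies", {
  pc <- data.frame(precision = c(0.5, 0.5, 0.5), recall = c(1, 1, 1),
                   f1 = c(2/3, 2/3, 2/3), auc = c(0.4, 0.4, 0.4))
  w <- weightedClassificationMetrics(pc, c(10, 1, 5))
  expect_equal(w$precision, 0.5)
  expect_equal(w$f1, 2/3)
  pc2 <- data.frame(precision = 0, recall = 0, f1 = c(1, 0, 0), auc = 0)
  w2 <- weightedClassificationMetrics(pc2, c(1519, 7989, 2272))
  expect_equal(w2$f1, 1519 / 11780)
  expect_error(weightedClassificationMetrics(pc, c(0, 0, 0)), "positive")
})

test_that("F1 is non-decreasing in the gold-standard radius", {
  lp <- layoutParams(height = 96, width = 96, nIpt = 2, nInt = 3, nNt = 2,
                     minSeparation = 26)
  lays <- lapply(1:2, function(s) sampleLayout(lp, s))
  maps <- lapply(lays, buildTargetMap, dims = c(96, 96))
  cfg <- evalConfig(radius = 16, etaGrid = c(0, 0.5, 1))

  tab <- radiusSensitivity(maps, lays, cfg)
  exact <- tab$f1[tab$mode == "detection"]
  expect_true(all(abs(exact - exact[1]) < 1e-12))

  # jitter detections by 10 px: r = 8 misses, r >= 12 recovers
  set.seed(5)
  for (s in 1:10) {
    inst <- randomInstance(100 + s, maxN = 6, span = 40)
    f1r <- vapply(c(8, 12, 16), function(r) {
      ct <- matchCounts(matchDetections(inst$det, inst$ann, r))
      prf(ct["tp"], ct["fp"], ct["fn"])[["f1"]]
    }, numeric(1))
    expect_true(all(diff(f1r) >= -1e-12))
  }
  jitterAnn <- data.frame(row = c(20, 50), col = c(20, 50),
                          label = c("IPT", "INT"))
  jitterDet <- data.frame(row = jitterAnn$row + c(10, -10),
                          col = jitterAnn$col, label = jitterAnn$label,
                          score = 1)
  f1j <- vapply(c(8, 12, 16), function(r) {
    ct <- matchCounts(matchDetections(jitterDet, jitterAnn, r))
    prf(ct["tp"], ct["fp"], ct["fn"])[["f1"]]
  }, numeric(1))
  expect_lt(f1j[1], f1j[2])
  expect_lte(f1j[2], f1j[3])
})

test_that("metricsReport pools counts and conserves totals", {
  lp <- layoutParams(height = 96, width = 96, nIpt = 2, nInt = 3, nNt = 2,
                     minSeparation = 26)
  lays <- lapply(1:3, function(s) sampleLayout(lp, s))
  maps <- lapply(lays, buildTargetMap, dims = c(96, 96))
  rep <- metricsReport(maps, lays, evalConfig(radius = 8,
                                              etaGrid = c(0, 0.5, 1)))
  d <- detectionMetrics(rep)
  expect_equal(d$f1, 1)
  expect_equal(d$tp + d$fn, sum(vapply(lays, nrow, numeric(1))))
  px <- pixelMetrics(rep)
  expect_equal(px$tp + px$fp + px$fn + px$tn, 3 * 96 * 96)
  expect_equal(sum(rep@classCounts), sum(vapply(lays, nrow, numeric(1))))
  w <- weightedMetrics(rep)
  expect_equal(w$f1, 1)
})
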