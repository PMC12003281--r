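test_that("IoU handles identity, disjointness and partial overlap", {
  a <- c(0.3, 0.3, 0.2, 0.2)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, c(0.8, 0.8, 0.1, 0.1)), 0.0)
  # two same-size boxes overlapping on half their area: 0.5 / (2 - 0.5)
  b1 <- c(0.25, 0.5, 0.2, 0.2)
  b2 <- c(0.35, 0.5, 0.2, 0.2)
  expect_equal(iou(b1, b2), 1 / 3, tolerance = 1e-12)
  # rasterized pixel-count oracle on a fine grid
  g <- 400
  px <- (seq_len(g) - 0.5) / g
  inb <- function(b, x, y) abs(x - b[1]) < b[3] / 2 & abs(y - b[2]) < b[4] / 2
  X <- matrix(rep(px, each = g), g); Y <- matrix(rep(px, times = g), g)
  i1 <- inb(b1, X, Y); i2 <- inb(b2, X, Y)
  expect_equal(iou(b1, b2), sum(i1 & i2) / sum(i1 | i2), tolerance = 1e-2)
})

test_that("greedy matching yields perfect and degenerate counts", {
  sc <- makeDetectionScenario(8, 0, 0, iouNoise = 0, seed = 4)
  res <- matchDetections(sc$dets, sc$gts)
  expect_equal(truePositives(res$counts), 8L)
  expect_equal(falsePositives(res$counts), 0L)
  expect_equal(falseNegatives(res$counts), 0L)
  empty <- detectionBoxes(integer(), numeric(), numeric(), numeric(),
                          numeric(), numeric())
  res <- matchDetections(empty, sc$gts)
  expect_equal(falseNegatives(res$counts), 8L)
})

test_that("matching equals an independent scalar oracle on small scenarios", {
  for (seed in 1:30) {
    n <- ATWquant:::.with_seed(seed, sample(1:6, 2, replace = TRUE))
    gts <- ATWquant:::.with_seed(seed + 1000, yoloBoxes(
      rep(0L, n[1]), stats::runif(n[1], 0.2, 0.8),
      stats::runif(n[1], 0.2, 0.8), stats::runif(n[1], 0.1, 0.3),
      stats::runif(n[1], 0.1, 0.3)))
    dets <- ATWquant:::.with_seed(seed + 2000, detectionBoxes(
      rep(0L, n[2]), stats::runif(n[2], 0.2, 0.8),
      stats::runif(n[2], 0.2, 0.8), stats::runif(n[2], 0.1, 0.3),
      stats::runif(n[2], 0.1, 0.3), stats::runif(n[2])))
    res <- matchDetections(dets, gts)
    oracle <- greedy_match_oracle(dets, gts)
    expect_equal(truePositives(res$counts), unname(oracle["tp"]))
    expect_equal(falsePositives(res$counts), unname(oracle["fp"]))
    expect_equal(falseNegatives(res$counts), unname(oracle["fn"]))
  }
})

test_that("matching is one-to-one and class-aware", {
  gts <- yoloBoxes(c(0L, 1L), c(0.3, 0.3), c(0.3, 0.3), c(0.2, 0.2),
                   c(0.2, 0.2))
  # both detections sit on the class-0 ground truth; one is class 1
  dets <- detectionBoxes(c(0L, 0L, 1L), c(0.3, 0.31, 0.3),
                         c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2),
                         c(0.2, 0.2, 0.2), c(0.9, 0.8, 0.7))
  res <- matchDetections(dets, gts)
  expect_equal(truePositives(res$counts), 2L)   # one per class
  expect_equal(falsePositives(res$counts), 1L)  # duplicate class-0 box
  expect_equal(sort(res$matches$gt), 1:2)
})

test_that("precision, recall and F1 identities hold", {
  expect_equal(precisionScore(824, 9), 824 / 833)
  expect_equal(recallScore(824, 106), 824 / 930)
  expect_equal(f1Score(0.5, 0.5), 0.5)
  expect_equal(f1Score(0, 0), 0)
  for (seed in 1:20) {
    pr <- ATWquant:::.with_seed(seed, stats::runif(2))
    f <- f1Score(pr[1], pr[2])
    expect_gte(f, 0)
    expect_lte(f, max(pr))
    expect_gte(f + 1e-12, min(pr))
  }
})

test_that("printed F1 cells follow from printed precision and recall", {
  expect_equal(round(100 * f1Score(0.947, 0.930), 1), 93.8)
  expect_equal(ATWquant:::.round_half_up(100 * f1Score(0.955, 0.851), 1),
               90.0)
})

test_that("AP matches the hand-enumerated precision-recall staircase", {
  # 3 ground truths; 4 ranked detections: hit, miss, hit, miss.
  gts <- yoloBoxes(rep(0L, 3), c(0.2, 0.5, 0.8), rep(0.5, 3),
                   rep(0.1, 3), rep(0.1, 3))
  dets <- detectionBoxes(rep(0L, 4),
                         c(0.2, 0.35, 0.5, 0.65), rep(0.5, 4),
                         rep(0.1, 4), rep(0.1, 4),
                         c(0.9, 0.8, 0.7, 0.6))
  # precision staircase 1, 1/2, 2/3, 1/2 at recalls 1/3, 1/3, 2/3, 2/3;
  # monotone envelope integrates to 1/3 * 1 + 1/3 * 2/3 = 5/9
  res <- averagePrecision(dets, gts)
  expect_equal(res$map, 5 / 9, tolerance = 1e-12)
})

test_that("AP endpoints and rescaling invariance", {
  sc <- makeDetectionScenario(10, 0, 0, seed = 6)
  expect_equal(averagePrecision(sc$dets, sc$gts)$map, 1.0)
  far <- sc$dets
  far$cx <- 0.02; far$cy <- 0.02       # tiny corner boxes, off every target
  far$w <- 0.02; far$h <- 0.02
  expect_equal(averagePrecision(far, sc$gts)$map, 0.0)
  sc2 <- makeDetectionScenario(12, 3, 4, seed = 7)
  base <- averagePrecision(sc2$dets, sc2$gts)$map
  resc <- sc2$dets
  resc$conf <- resc$conf^3                     # strictly increasing map
  expect_equal(averagePrecision(resc, sc2$gts)$map, base,
               tolerance = 1e-12)
  expect_error(averagePrecision(sc2$dets, sc2$gts[0, ]), "ground truth")
})

test_that("field accounting reproduces the printed field-test rows", {
  f <- fieldCounts(930, evalCounts(tp = 824, fp = 9, fn = 106))
  expect_equal(f$detected, 833L)
  expect_equal(f$missedRate, 11.4)
  expect_equal(f$falseRate, 1.0)
  f2 <- fieldCounts(930, evalCounts(tp = 923, fp = 3, fn = 7))
  expect_equal(f2$detected, 926L)
  expect_equal(f2$missedRate, 0.8)
  expect_equal(f2$falseRate, 0.3)
  # self-consistency: detected - false + missed = nGt, for both rows
  for (x in list(f, f2))
    expect_equal(x$detected - x$falseDets + x$missed, x$nGt)
  f0 <- fieldCounts(50, evalCounts(50, 0, 0))
  expect_equal(f0$detected, 50L)
  expect_equal(f0$missedRate, 0)
  expect_error(fieldCounts(0, evalCounts(0, 0, 0)), "positive")
  expect_error(fieldCounts(10, evalCounts(5, 0, 2)), "equal nGt")
})

test_that("prediction files round-trip through the readers", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.90 0.300000 0.400000 0.100000 0.200000",
               "1 0.50 0.700000 0.600000 0.050000 0.050000"), tmp)
  d <- readPredictions(tmp)
  expect_equal(d$conf, c(0.9, 0.5))
  expect_equal(d$class_id, c(0L, 1L))
  writeLines("0 0.9 0.5 0.5", tmp)
  expect_error(readPredictions(tmp), "expected 6 fields")
})

test_that("dataset-level evaluation pools images correctly", {
  sc1 <- makeDetectionScenario(20, 2, 1, seed = 11)
  sc2 <- makeDetectionScenario(30, 3, 2, seed = 12)
  res <- evalDetections(list(sc1$gts, sc2$gts), list(sc1$dets, sc2$dets))
  expect_equal(truePositives(res$counts), 45L)
  expect_equal(falsePositives(res$counts), 3L)
  expect_equal(falseNegatives(res$counts), 5L)
  expect_equal(res$precision, 45 / 48)
  expect_equal(res$recall, 45 / 50)
  expect_equal(res$field$nGt, 50L)
  expect_gte(res$ap50, 0.8)
})
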