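mkFeat <- function(xy, level, w = 250, h = 250) {
  n <- nrow(xy)
  f <- data.frame(x = xy[, 1], y = xy[, 2], level = rep(level, n),
                  sigma = rep(sqrt(2^(level - 1)), n), response = rep(1, n),
                  polarity = rep("dark", n), stringsAsFactors = FALSE)
  attr(f, "imageWidth") <- w
  attr(f, "imageHeight") <- h
  f
}

test_that("feature pooling unions per-image sets and normalizes positions", {
  s1 <- mkFeat(cbind(c(10, 20), c(10, 20)), 4L)
  s2 <- mkFeat(cbind(numeric(0), numeric(0)), 4L)
  s3 <- mkFeat(cbind(seq(30, 70, 10), seq(30, 70, 10)), 4L)
  pooled <- accumulateFeatures(list(s1, s2, s3), level = 4L)
  expect_identical(nrow(pooled), 7L)  # 2 + 0 + 5
  # pixel (125, 125) of a 250x250 image lands at (0.5, 0.5)
  p <- accumulateFeatures(list(mkFeat(cbind(125, 125), 2L)), level = 2L)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  # order invariance of the pooled multiset
  a <- accumulateFeatures(list(s1, s3), level = 4L)
  b <- accumulateFeatures(list(s3, s1), level = 4L)
  expect_equal(a[order(a[, 1]), ], b[order(b[, 1]), ], ignore_attr = TRUE)
  # points from other levels are excluded
  expect_identical(nrow(accumulateFeatures(list(s1), level = 5L)), 0L)
})

test_that("density estimates are proper, deterministic and localized", {
  set.seed(2)
  pts <- cbind(0.5 + rnorm(100, 0, 0.004), 0.5 + rnorm(100, 0, 0.004))
  m <- estimateDensity(pts, 128)
  cell <- 1 / 128^2
  expect_lt(abs(sum(densityGrid(m)) * cell - 1), 1e-6)
  expect_true(all(densityGrid(m) >= 0))
  am <- which(densityGrid(m) == max(densityGrid(m)), arr.ind = TRUE)[1, ]
  expect_lt(max(abs((am - 0.5) / 128 - 0.5)), 1.5 / 128)
  expect_identical(densityGrid(m), densityGrid(estimateDensity(pts, 128)))
  expect_error(estimateDensity(cbind(0.5, 0.5)), "insufficient")
})

test_that("a two-component mixture is recovered by the two largest density modes", {
  set.seed(42)
  mu <- rbind(c(0.3, 0.35), c(0.7, 0.6))
  z <- sample(1:2, 500, replace = TRUE)
  pts <- mu[z, ] + matrix(rnorm(1000, 0, 0.04), 500, 2)
  pts <- pmin(pmax(pts, 0), 1)
  m <- selectModelPoints(estimateDensity(pts, 128), ratio = 0.5)
  mp <- modelPoints(m)[1:2, , drop = FALSE]
  d <- sapply(1:2, function(i) min(sqrt(rowSums((mp - matrix(mu[i, ], 2, 2,
              byrow = TRUE))^2))))
  expect_lt(max(d), 0.05)
})

test_that("similarity indices behave as distribution overlap measures", {
  set.seed(3)
  g1 <- matrix(runif(64 * 64), 64); g1 <- g1 / (sum(g1) / 64^2)
  for (meth in c("bray_curtis", "one_minus_jsd")) {
    expect_equal(mapSimilarity(g1, g1, meth), 1)
    g2 <- matrix(runif(64 * 64), 64)
    expect_equal(mapSimilarity(g1, g2, meth), mapSimilarity(g2, g1, meth))
    expect_gte(mapSimilarity(g1, g2, meth), 0)
    expect_lt(mapSimilarity(g1, g2, meth), 1)
  }
  # disjoint supports: Bray-Curtis 0
  a <- matrix(0, 8, 8); a[1:4, ] <- 1
  b <- matrix(0, 8, 8); b[5:8, ] <- 1
  expect_equal(mapSimilarity(a, b, "bray_curtis"), 0)
  expect_equal(mapSimilarity(a, b, "one_minus_jsd"), 0)
  # discretized p = (1/2, 1/2) vs q = (1, 0)
  expect_equal(mapSimilarity(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1),
                             "bray_curtis"), 0.5)
  expect_error(mapSimilarity(matrix(0.5, 2, 2), matrix(0.5, 3, 3)),
               "mismatched")
})

test_that("model point selection applies the fraction-of-maximum rule", {
  xs <- (seq_len(64) - 0.5) / 64
  X <- matrix(xs, 64, 64); Y <- t(X)
  bump <- function(cx, cy, a) a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 0.05^2))
  cc <- function(i) (i - 0.5) / 64  # align bump centers with grid cells
  g <- bump(cc(16), cc(16), 1) + bump(cc(48), cc(16), 0.8) +
    bump(cc(32), cc(48), 0.6)
  m <- new("FeatureDensityMap", level = 2L, grid = g / (sum(g) / 64^2),
           nImages = 1L, bandwidth = 0.05,
           modelPoints = matrix(numeric(0), 0, 2))
  sel <- modelPoints(selectModelPoints(m, 0.7))
  expect_identical(nrow(sel), 2L)  # peaks at 1.0 and 0.8 pass, 0.6 fails
  expect_true(all(modelPoints(selectModelPoints(m, 0.7)) >= 0 &
                  modelPoints(selectModelPoints(m, 0.7)) <= 1))
  # every selected point is at least the threshold fraction of the max
  idx <- cbind(round(sel[, 1] * 64 + 0.5), round(sel[, 2] * 64 + 0.5))
  expect_true(all(g[idx] >= 0.7 * max(g) - 1e-9))
  # single peak -> exactly one point; ratio 1 -> only the argmax
  m1 <- new("FeatureDensityMap", level = 2L,
            grid = (g0 <- bump(cc(32), cc(32), 1)) / (sum(g0) / 64^2),
            nImages = 1L, bandwidth = 0.05,
            modelPoints = matrix(numeric(0), 0, 2))
  expect_identical(nrow(modelPoints(selectModelPoints(m1))), 1L)
  expect_identical(nrow(modelPoints(selectModelPoints(m, 1))), 1L)
  flat <- new("FeatureDensityMap", level = 2L, grid = matrix(1, 64, 64),
              nImages = 1L, bandwidth = 0.05,
              modelPoints = matrix(numeric(0), 0, 2))
  expect_error(selectModelPoints(flat), "degenerate")
})

test_that("a stream of identical images converges immediately", {
  img <- generateFaceImage(faceSpec(seed = 4, canvas = 120))$image
  f <- extractFeatures(img)
  curve <- convergenceCurve(rep(list(f), 8), level = 2L, startN = 5L,
                            gridResolution = 64L)
  expect_equal(curve$bray_curtis, rep(1, 3))
  expect_equal(curve$one_minus_jsd, rep(1, 3))
  expect_error(convergenceCurve(rep(list(f), 3), level = 2L, startN = 5L),
               "more than")
})

test_that("the two similarity indices are consistent along a face stream", {
  feats <- fxFaceFeatures()[1:45]
  curve <- convergenceCurve(feats, level = 2L, startN = 15L,
                            gridResolution = 64L)
  expect_true(all(curve$bray_curtis > 0 & curve$bray_curtis <= 1))
  expect_gt(suppressWarnings(
    cor(curve$bray_curtis, curve$one_minus_jsd, method = "spearman")), 0.9)
})

test_that("density maps of mirrored face sets are mirror images", {
  imgs <- fxFaceImages()[1:40]
  feats <- fxFaceFeatures()[1:40]
  mirFeats <- lapply(imgs, function(im) extractFeatures(im[nrow(im):1, ]))
  m1 <- estimateDensity(accumulateFeatures(feats, 2L), 64)
  m2 <- estimateDensity(accumulateFeatures(mirFeats, 2L), 64)
  p <- densityGrid(m1) / sum(densityGrid(m1))
  q <- densityGrid(m2) / sum(densityGrid(m2))
  tv <- 0.5 * sum(abs(p - q[nrow(q):1, ]))
  expect_lt(tv, 0.05)
})

test_that("fine-scale model points concentrate on the facial landmarks", {
  feats <- fxFaceFeatures()
  lm <- faceSpec()$landmarks
  for (k in 2:4) {
    mp <- modelPoints(selectModelPoints(
      estimateDensity(accumulateFeatures(feats, k), 128, level = k)))
    dmin <- apply(mp, 1, function(p)
      min(vapply(lm, function(l) sqrt(sum((p - l)^2)), numeric(1))))
    expect_gte(mean(dmin < 0.08), 0.5)
  }
})

test_that("density maps survive a JSON round trip and export as heatmaps", {
  set.seed(5)
  m <- selectModelPoints(estimateDensity(matrix(runif(200), 100, 2), 32,
                                         level = 3L, nImages = 10L))
  path <- withr::local_tempfile(fileext = ".json")
  writeDensityMap(m, path)
  back <- readDensityMap(path)
  expect_equal(densityGrid(back), densityGrid(m), tolerance = 1e-12)
  expect_equal(modelPoints(back), modelPoints(m), ignore_attr = TRUE)
  expect_identical(nImages(back), 10L)
  png <- withr::local_tempfile(fileext = ".png")
  exportDensityMapPNG(m, png)
  expect_true(file.exists(png))
})
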