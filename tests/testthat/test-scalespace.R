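test_that("pyramid follows the sigma schedule and halves the grid every two levels", {
  set.seed(1)
  pyr <- buildPyramid(matrix(runif(250 * 250), 250), nLevels = 10)
  sig <- scaleSigma(pyr)
  expect_equal(sig, sqrt(2^(0:9)))
  expect_equal(sig[1], 1)
  expect_equal(sig[10], 16 * sqrt(2))
  # sigma doubles every two levels
  expect_equal(sig[3:10] / sig[1:8], rep(2, 8))
  g <- vapply(scaleLevels(pyr), gridDownsample, integer(1))
  expect_identical(g, as.integer(2^((0:9) %/% 2)))
  dims <- vapply(scaleLevels(pyr), function(l) nrow(smoothedImage(l)), integer(1))
  expect_identical(dims[3], 125L)  # 250 px input carried at half size
  expect_identical(dims[4], 125L)
})

test_that("degenerate inputs are handled: constant image, undersized image", {
  pyr <- buildPyramid(matrix(0.5, 60, 60), nLevels = 6)
  for (l in scaleLevels(pyr))
    expect_lt(max(abs(laplacianResponse(l))), 1e-9)
  expect_identical(nrow(detectExtrema(scaleLevels(pyr)[[3]])), 0L)
  expect_error(buildPyramid(matrix(0, 10, 10)), "too small")
})

test_that("incremental smoothing on the downsampled grid tracks direct native convolution", {
  set.seed(7)
  base <- gazeface:::gaussianSmooth(matrix(runif(120 * 120), 120), 2)  # band-limited
  pyr <- buildPyramid(base, nLevels = 4)
  # level 4: sigma = 2*sqrt(2), grid half; oracle smooths at native scale
  direct <- gazeface:::downsample2(gazeface:::gaussianSmooth(base, sqrt(8)))
  got <- smoothedImage(scaleLevels(pyr)[[4]])
  relerr <- max(abs(got - direct)) / diff(range(direct))
  expect_lt(relerr, 0.01)
})

test_that("normalized Laplacian of a Gaussian blob peaks at the matching scale", {
  # closed form: the scale-normalized LoG magnitude at a blob's center is
  # maximal when sigma equals the blob width; width 4 px -> level 5
  pyr <- buildPyramid(renderBlob(100, 4), nLevels = 10)
  resp <- vapply(laplacianResponse(pyr), max, numeric(1))
  expect_identical(which.max(resp), 5L)
  # localized extremum of matching polarity near the center
  e <- detectExtrema(scaleLevels(pyr)[[5]])
  top <- e[which.max(e$response), ]
  g <- gridDownsample(scaleLevels(pyr)[[5]])
  expect_lt(abs(top$x - 49.5), 2 * g)
  expect_lt(abs(top$y - 49.5), 2 * g)
  expect_identical(top$polarity, "dark")
})

test_that("bright blobs carry bright polarity (negative-definite Hessian)", {
  pyr <- buildPyramid(renderBlob(100, 4, dark = FALSE), nLevels = 6)
  e <- detectExtrema(scaleLevels(pyr)[[5]])
  expect_identical(e$polarity[which.max(e$response)], "bright")
})

test_that("upsampling a blob by two shifts the argmax level by exactly two", {
  a <- vapply(laplacianResponse(buildPyramid(renderBlob(100, 4), 10)), max,
              numeric(1))
  b <- vapply(laplacianResponse(buildPyramid(renderBlob(200, 8), 10)), max,
              numeric(1))
  expect_identical(which.max(b) - which.max(a), 2L)
})

test_that("detected extrema equal a brute-force neighborhood scan", {
  set.seed(11)
  imgs <- list(gazeface:::gaussianSmooth(matrix(runif(80 * 80), 80), 1.5),
               renderBlob(60, 3),
               generateFaceImage(faceSpec(seed = 5, canvas = 100))$image)
  for (img in imgs) for (k in c(2L, 4L)) {
    lvl <- scaleLevels(buildPyramid(img, nLevels = k))[[k]]
    got <- detectExtrema(lvl)
    want <- bruteForceExtrema(lvl)
    expect_identical(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      o1 <- order(got$x, got$y); o2 <- order(want[, 1], want[, 2])
      expect_equal(got$x[o1], want[o2, 1])
      expect_equal(got$y[o1], want[o2, 2])
    }
  }
})

test_that("a step edge yields no extrema after the definiteness filter", {
  img <- matrix(0.2, 80, 80)
  img[41:80, ] <- 0.8
  pyr <- buildPyramid(img, nLevels = 4)
  for (l in scaleLevels(pyr))
    expect_identical(nrow(detectExtrema(l, minResponse = 0)), 0L)
})

test_that("feature extraction is equivariant under 90-degree rotation", {
  img <- generateFaceImage(faceSpec(seed = 9, canvas = 100))$image
  rot <- t(img)[, nrow(img):1]  # (x, y) -> (y, W-1-x)
  f1 <- extractFeatures(img, nLevels = 6)
  f2 <- extractFeatures(rot, nLevels = 6)
  expect_identical(nrow(f1), nrow(f2))
  mapped <- data.frame(x = f1$y, y = nrow(img) - 1 - f1$x)
  o1 <- order(mapped$x, mapped$y); o2 <- order(f2$x, f2$y)
  expect_lt(max(abs(mapped$x[o1] - f2$x[o2])), 1 + 1e-9)
  expect_lt(max(abs(mapped$y[o1] - f2$y[o2])), 1 + 1e-9)
})

test_that("scale linking keeps the strongest member of a chain", {
  mk <- function(x, y, level, response) data.frame(
    x = x, y = y, level = level, sigma = sqrt(2^(level - 1)),
    response = response, polarity = "dark", stringsAsFactors = FALSE)
  # one blob seen at levels 4, 5, 6: only the level-5 point survives
  chain <- rbind(mk(50, 50, 4L, 0.4), mk(50.5, 50, 5L, 0.9), mk(49, 51, 6L, 0.5))
  out <- linkScales(chain)
  expect_identical(nrow(out), 1L)
  expect_identical(out$level, 5L)
  expect_equal(out$response, 0.9)
  # a single point passes through unchanged
  single <- mk(10, 10, 3L, 0.2)
  expect_equal(linkScales(single), single)
  # blobs farther apart than the linking radius survive separately
  far <- rbind(mk(20, 20, 4L, 0.4), mk(80, 80, 5L, 0.9))
  expect_identical(nrow(linkScales(far)), 2L)
  # opposite polarity never links
  mixed <- rbind(mk(50, 50, 4L, 0.4),
                 transform(mk(50, 50, 5L, 0.9), polarity = "bright"))
  expect_identical(nrow(linkScales(mixed)), 2L)
})

test_that("linking is an exhaustive-chain oracle on small configurations", {
  # brute force: connected components over the adjacent-level linking
  # relation, keeping each component's strongest point
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    pts <- data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60),
                      level = sample(3:6, n, replace = TRUE))
    pts$sigma <- sqrt(2^(pts$level - 1))
    pts$response <- runif(n)
    pts$polarity <- sample(c("dark", "bright"), n, replace = TRUE)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (abs(pts$level[i] - pts$level[j]) != 1L) next
      r <- 2 * sqrt(2^(max(pts$level[i], pts$level[j]) - 1))
      d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
      if (d <= r && pts$polarity[i] == pts$polarity[j])
        adj[i, j] <- adj[j, i] <- TRUE
    }
    comp <- seq_len(n)
    repeat {
      new <- comp
      for (i in 1:n) for (j in 1:n) if (adj[i, j])
        new[i] <- new[j] <- min(new[i], new[j])
      if (identical(new, comp)) break
      comp <- new
    }
    want <- sort(vapply(split(seq_len(n), comp),
                        function(ix) ix[which.max(pts$response[ix])],
                        integer(1)))
    got <- linkScales(pts)
    expect_equal(sort(got$response), sort(pts$response[want]))
  }
})

test_that("feature points serialize to the documented CSV dialect", {
  f <- extractFeatures(renderBlob(60, 3), nLevels = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeaturesCSV(f, path, imageId = "blob")
  back <- readFeaturesCSV(path)
  expect_identical(names(back),
                   c("image_id", "x", "y", "level", "sigma", "response",
                     "polarity"))
  expect_equal(back$x, f$x)
  expect_equal(back$response, f$response, tolerance = 1e-6)
})
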