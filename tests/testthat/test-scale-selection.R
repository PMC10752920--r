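test_that("fixations partition into 12 per-index sets", {
  set.seed(1)
  n <- 200
  rec <- data.frame(observer_id = sample(1:5, n, TRUE),
                    image_id = sample(1:10, n, TRUE),
                    fixation_index = sample(1:14, n, TRUE),
                    x = runif(n), y = runif(n))
  fs <- new("FixationSet", records = rec)
  sets <- suppressWarnings(partitionFixations(fs, 12L))
  expect_length(sets, 12L)
  expect_identical(sum(vapply(sets, nrow, integer(1))),
                   sum(rec$fixation_index <= 12))  # 13th/14th dropped
  expect_identical(nrow(sets[[3]]), sum(rec$fixation_index == 3))
  empty <- new("FixationSet",
               records = rec[0, ])
  expect_length(suppressWarnings(partitionFixations(empty)), 12L)
})

test_that("the full observer cohort contributes one first fixation per image", {
  lm <- faceSpec()$landmarks
  fx <- generateFixations(do.call(rbind, lm), observerModels(20L, seed = 2),
                          nImages = 120L, seed = 3)
  sets <- partitionFixations(fx)
  expect_identical(nrow(sets[[1]]), 20L * 120L)  # |F_1| = 2400
  expect_true(all(vapply(sets, nrow, integer(1)) == 2400L))
})

test_that("k-means with Davies-Bouldin selection recovers planted clusters", {
  set.seed(5)
  mu <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.5, 0.8))
  sdc <- 0.02  # separation ~ 10x the cluster sd
  z <- sample(1:3, 600, TRUE)
  pts <- mu[z, ] + matrix(rnorm(1200, 0, sdc), 600)
  cs <- clusterPoints(pts, seed = 9)
  expect_identical(cs$nClusters, 3L)
  for (i in 1:3) {
    d <- min(sqrt(rowSums((cs$centers - matrix(mu[i, ], cs$nClusters, 2,
                                               byrow = TRUE))^2)))
    # 2-D norm of the mean of ~200 points: SE = sd * sqrt(2/n)
    expect_lt(d, 3 * sdc * sqrt(2 / 200))
  }
  # all-identical points collapse to a single cluster at that point
  same <- matrix(0.4, 50, 2)
  cs1 <- clusterPoints(same, seed = 1)
  expect_identical(cs1$nClusters, 1L)
  expect_equal(as.numeric(cs1$centers), c(0.4, 0.4))
  # k stays inside [1, 7] even for diffuse data
  set.seed(6)
  diffuse <- matrix(runif(400), 200)
  kk <- clusterPoints(diffuse, seed = 2)$nClusters
  expect_gte(kk, 1L); expect_lte(kk, 7L)
  expect_error(clusterPoints(matrix(numeric(0), 0, 2)), "insufficient")
})

test_that("Davies-Bouldin prefers the correct structure and rejects k = 1", {
  set.seed(7)
  mu <- rbind(c(0.2, 0.5), c(0.8, 0.5))
  pts <- mu[sample(1:2, 300, TRUE), ] + matrix(rnorm(600, 0, 0.03), 300)
  km2 <- kmeans(pts, 2, nstart = 5)
  km4 <- kmeans(pts, 4, nstart = 5)
  expect_lt(daviesBouldin(pts, km2$cluster, km2$centers),
            daviesBouldin(pts, km4$cluster, km4$centers))
  expect_error(daviesBouldin(pts, rep(1, 300), matrix(0.5, 1, 2)),
               "undefined")
})

test_that("cluster distance is the mean nearest-center distance, feature to fixation", {
  a <- list(centers = matrix(c(0, 0), 1, 2))
  expect_equal(clusterDistance(a, a), 0)
  b <- list(centers = matrix(c(0.3, 0.4), 1, 2))
  expect_equal(clusterDistance(a, b), 0.5)  # 3-4-5 triangle
  f <- list(centers = rbind(c(0, 0), c(1, 1)))
  expect_equal(clusterDistance(f, a), (0 + sqrt(2)) / 2)
  # not symmetric by construction
  expect_equal(clusterDistance(a, f), 0)
  expect_error(clusterDistance(list(centers = matrix(numeric(0), 0, 2)), a),
               "empty")
})

test_that("the affinity profile dips at the scale whose clusters match the fixations", {
  set.seed(11)
  base <- rbind(c(0.3, 0.35), c(0.7, 0.35), c(0.5, 0.75))
  mkCloud <- function(shift) {
    ctrs <- base + matrix(rep(shift, each = 3), 3)
    ctrs[sample(1:3, 400, TRUE), ] + matrix(rnorm(800, 0, 0.02), 400)
  }
  feats <- list("3" = mkCloud(c(0.15, 0.1)), "4" = mkCloud(c(0, 0)),
                "5" = mkCloud(c(-0.12, 0.08)))
  fix <- lapply(1:4, function(i)
    base[sample(1:3, 300, TRUE), ] + matrix(rnorm(600, 0, 0.02), 300))
  prof <- scaleAffinityProfile(feats, fix, nRep = 5L, seed = 21L)
  expect_identical(prof$levels[which.min(prof$d)], 4L)
  expect_true(all(prof$d >= 0))
  expect_identical(dim(prof$dki), c(3L, 4L))
  expect_equal(prof$d, rowMeans(prof$dki), tolerance = 1e-9)
})

test_that("profile means are stable in the number of repetitions", {
  set.seed(13)
  mu <- rbind(c(0.25, 0.3), c(0.75, 0.3), c(0.5, 0.8))
  cloud <- function(n, sd) mu[sample(1:3, n, TRUE), ] +
    matrix(rnorm(2 * n, 0, sd), n)
  feats <- list("2" = cloud(200, 0.03), "3" = cloud(200, 0.05))
  fix <- list(cloud(150, 0.03), cloud(150, 0.04))
  p1 <- scaleAffinityProfile(feats, fix, nRep = 10L, seed = 5L)
  p2 <- scaleAffinityProfile(feats, fix, nRep = 20L, seed = 6L)
  se <- p1$sd / sqrt(p1$nRep)
  expect_true(all(abs(p1$d - p2$d) <= 2 * pmax(se, 1e-3)))
})

test_that("scale selection returns local minima, endpoints included", {
  expect_identical(selectScales(c(5, 3, 4, 2, 3)), c(4L, 2L))
  expect_identical(selectScales(c(5, 4, 3, 2, 1)), 5L)  # endpoint rule
  expect_identical(selectScales(c(1, 2, 3, 4, 5)), 1L)
  # reference configuration: minima at levels 4, 7 and 10, with the
  # coarsest excluded by the usable range -> scales {7, 4}
  d10 <- c(0.9, 0.8, 0.7, 0.3, 0.5, 0.6, 0.2, 0.4, 0.5, 0.1)
  expect_identical(selectScales(list(levels = 1:10, d = d10),
                                usableLevels = 1:7), c(7L, 4L))
  expect_error(selectScales(rep(1, 5)), "no qualifying")
  expect_error(selectScales(c(1, 2)), "at least 3")
})

test_that("profiles are invariant to observer/image permutation within a fixation set", {
  set.seed(17)
  mu <- rbind(c(0.2, 0.3), c(0.8, 0.7))
  feats <- list("2" = mu[sample(1:2, 100, TRUE), ] +
                  matrix(rnorm(200, 0, 0.02), 100))
  fixA <- list(mu[sample(1:2, 60, TRUE), ] + matrix(rnorm(120, 0, 0.02), 60))
  fixB <- list(fixA[[1]][sample(60), ])
  pA <- scaleAffinityProfile(feats, fixA, nRep = 3L, seed = 8L)
  pB <- scaleAffinityProfile(feats, fixB, nRep = 3L, seed = 8L)
  expect_equal(pA$d, pB$d, tolerance = 1e-6)
})
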