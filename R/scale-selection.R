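#' Partition fixations by fixation index
#'
#' Splits fixation records into per-index point sets: set i contains the
#' normalized positions of the i-th fixation of every observer on every
#' image, pooled. Records with index greater than `maxIndex` are dropped.
#'
#' @param fixations a [FixationSet-class] (or its records data.frame).
#' @param maxIndex number of sets to return (default 12).
#' @return list of `maxIndex` two-column matrices of (x, y) positions.
#' @export
partitionFixations <- function(fixations, maxIndex = 12L) {
  r <- if (is(fixations, "FixationSet")) fixations@records else fixations
  out <- lapply(seq_len(maxIndex), function(i) {
    s <- r[r$fixation_index == i, , drop = FALSE]
    cbind(x = s$x, y = s$y)
  })
  if (any(vapply(out, nrow, integer(1)) == 0L))
    warning("some fixation index sets are empty")
  out
}

#' Davies-Bouldin index of a clustering
#'
#' Cluster-validity score (lower is better): the mean over clusters of the
#' worst-case ratio of summed within-cluster scatter to between-center
#' separation. Undefined for k = 1.
#'
#' @param points two-column matrix.
#' @param assignment integer cluster label per point.
#' @param centers k x 2 matrix of cluster centers.
#' @return the index (non-negative; `Inf` if two centers coincide).
#' @export
daviesBouldin <- function(points, assignment, centers) {
  k <- nrow(centers)
  if (k < 2L) stop("Davies-Bouldin index is undefined for fewer than 2 clusters")
  S <- vapply(seq_len(k), function(i) {
    p <- points[assignment == i, , drop = FALSE]
    if (!nrow(p)) return(0)
    mean(sqrt(rowSums((p - matrix(centers[i, ], nrow(p), 2, byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centers))
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Cluster a 2-D point set with an adaptive number of clusters
#'
#' Runs k-means (10 restarts by default) for every k in `kRange` and keeps
#' the clustering minimizing the Davies-Bouldin index. Because the index is
#' undefined at k = 1, a single cluster (the centroid) is returned only when
#' the best k >= 2 clustering is itself poor (Davies-Bouldin above
#' `k1Threshold`), or when no k >= 2 is feasible. Values of k exceeding the
#' number of distinct points are skipped. Deterministic given `seed`.
#'
#' @param points two-column matrix of (x, y) positions.
#' @param kRange integer range of candidate cluster counts (default 1:7).
#' @param nInit number of k-means restarts (default 10).
#' @param seed integer seed.
#' @param k1Threshold Davies-Bouldin value above which the single-centroid
#'   solution is preferred (default 1.5).
#' @return list with `centers` (k x 2 matrix), `nClusters`,
#'   `daviesBouldin` (NA for k = 1) and `inertia` (total within-cluster sum
#'   of squares).
#' @export
clusterPoints <- function(points, kRange = 1:7, nInit = 10L, seed = 1L,
                          k1Threshold = 1.5) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("insufficient data: no points to cluster")
  nDistinct <- nrow(unique(points))
  centroid <- matrix(colMeans(points), 1, 2)
  single <- list(centers = centroid, nClusters = 1L,
                 daviesBouldin = NA_real_,
                 inertia = sum((points - centroid[rep(1, nrow(points)), ])^2))
  ks <- kRange[kRange >= 2L & kRange <= nDistinct]
  if (!length(ks)) {
    if (1L %in% kRange || nDistinct == 1L) return(single)
    stop("insufficient data: no feasible number of clusters in kRange")
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (k in ks) {
    km <- tryCatch(stats::kmeans(points, centers = k, nstart = nInit,
                                 iter.max = 50L),
                   error = function(e) NULL)
    if (is.null(km)) next
    db <- daviesBouldin(points, km$cluster, km$centers)
    if (is.null(best) || db < best$daviesBouldin)
      best <- list(centers = unname(km$centers), nClusters = k,
                   daviesBouldin = db, inertia = km$tot.withinss)
  }
  if (is.null(best)) return(single)
  if ((1L %in% kRange) && best$daviesBouldin > k1Threshold) return(single)
  best
}

#' Distance from feature clusters to fixation clusters
#'
#' For each feature cluster center, finds the closest fixation cluster
#' center and returns the mean of these nearest-center Euclidean distances.
#' Directed (feature to fixation) by construction.
#'
#' @param featureClusters,fixationClusters cluster summaries from
#'   [clusterPoints] (or bare center matrices).
#' @return non-negative mean nearest-center distance.
#' @export
clusterDistance <- function(featureClusters, fixationClusters) {
  a <- if (is.list(featureClusters)) featureClusters$centers else featureClusters
  b <- if (is.list(fixationClusters)) fixationClusters$centers else fixationClusters
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("empty cluster center list")
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  mean(sqrt(apply(d2, 1, min)))
}

#' Scale-to-fixation affinity profile
#'
#' For each scale k, clusters the pooled feature points; for each fixation
#' index i, clusters the fixation set; computes the directed cluster
#' distance d(k, i); averages over i to obtain d(k). The whole procedure is
#' repeated `nRep` times with fresh k-means initializations and the
#' repetition mean (with standard deviation) is reported.
#'
#' @param featuresByScale named list (by level) of two-column point matrices.
#' @param fixationSets list of per-index point matrices (see
#'   [partitionFixations]); empty sets are skipped.
#' @param nRep repetitions (default 100).
#' @param seed integer seed.
#' @param kRange,nInit,k1Threshold passed to [clusterPoints].
#' @return list with `levels`, `d` (mean profile), `sd` (per-level spread
#'   over repetitions), `dki` (levels x indices matrix of mean d(k, i)) and
#'   `nRep`.
#' @export
scaleAffinityProfile <- function(featuresByScale, fixationSets, nRep = 100L,
                                 seed = 1L, kRange = 1:7, nInit = 10L,
                                 k1Threshold = 1.5) {
  lv <- as.integer(names(featuresByScale))
  if (any(is.na(lv))) lv <- seq_along(featuresByScale)
  keepF <- vapply(fixationSets, nrow, integer(1)) > 0L
  if (!any(keepF)) stop("all fixation sets are empty")
  nk <- length(featuresByScale); ni <- length(fixationSets)
  acc <- matrix(0, nk, ni)
  dreps <- matrix(NA_real_, nk, nRep)
  for (rep in seq_len(nRep)) {
    s0 <- (as.integer(seed) + 7919L * rep) %% .Machine$integer.max
    fc <- lapply(seq_len(nk), function(j)
      clusterPoints(featuresByScale[[j]], kRange, nInit, seed = s0 + j,
                    k1Threshold = k1Threshold))
    xc <- lapply(seq_len(ni), function(i) {
      if (!keepF[i]) return(NULL)
      clusterPoints(fixationSets[[i]], kRange, nInit, seed = s0 + 100L + i,
                    k1Threshold = k1Threshold)
    })
    for (j in seq_len(nk)) {
      dki <- vapply(seq_len(ni), function(i)
        if (keepF[i]) clusterDistance(fc[[j]], xc[[i]]) else NA_real_,
        numeric(1))
      acc[j, ] <- acc[j, ] + ifelse(is.na(dki), 0, dki)
      dreps[j, rep] <- mean(dki, na.rm = TRUE)
    }
  }
  d <- rowMeans(dreps)
  list(levels = lv, d = d,
       sd = apply(dreps, 1, stats::sd),
       dki = acc / nRep, nRep = nRep)
}

#' Select model scales from an affinity profile
#'
#' Returns the levels at which the averaged distance profile d(k) has a
#' local minimum: interior levels strictly smaller than both neighbors,
#' endpoints smaller than their single neighbor. The result is intersected
#' with `usableLevels` and ordered coarse-to-fine (decreasing level).
#'
#' @param profile result of [scaleAffinityProfile] (or a bare numeric vector
#'   of distances, taken to be over levels 1..n).
#' @param usableLevels levels the model may use (default: all in profile).
#' @return integer vector of selected levels, coarse first.
#' @export
selectScales <- function(profile, usableLevels = NULL) {
  if (is.numeric(profile)) profile <- list(levels = seq_along(profile), d = profile)
  d <- profile$d; lv <- profile$levels
  n <- length(d)
  if (n < 3L) stop("profile must cover at least 3 scales")
  isMin <- logical(n)
  isMin[1] <- d[1] < d[2]
  isMin[n] <- d[n] < d[n - 1]
  if (n > 2L) for (j in 2:(n - 1L)) isMin[j] <- d[j] < d[j - 1] && d[j] < d[j + 1]
  sel <- lv[isMin]
  if (!is.null(usableLevels)) sel <- intersect(sel, usableLevels)
  if (!length(sel))
    stop("no qualifying local minimum: the profile selects no scales")
  sort(sel, decreasing = TRUE)
}
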