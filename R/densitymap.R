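#' Pool feature points across images at one scale
#'
#' Forms the multiset union of the feature points detected at the given
#' scale level over a collection of face images, with every position
#' normalized to the unit face frame \eqn{[0,1]^2} by its source image
#' width/height.
#'
#' @param featureSets list of per-image feature data.frames (as returned by
#'   [extractFeatures], which records the source dimensions as attributes
#'   `imageWidth`/`imageHeight`); alternatively pass `width`/`height` to
#'   apply one size to all sets.
#' @param level scale level whose points are pooled.
#' @param width,height optional common source image size, used for sets that
#'   do not carry their own dimensions.
#' @return two-column matrix of normalized (x, y) positions.
#' @export
accumulateFeatures <- function(featureSets, level, width = NULL, height = NULL) {
  if (is.data.frame(featureSets)) featureSets <- list(featureSets)
  pts <- lapply(featureSets, function(f) {
    w <- attr(f, "imageWidth"); h <- attr(f, "imageHeight")
    if (is.null(w)) w <- width
    if (is.null(h)) h <- height
    if (is.null(w) || is.null(h))
      stop("feature set carries no source image dimensions; pass width/height")
    f <- f[f$level == level, , drop = FALSE]
    cbind(f$x / w, f$y / h)
  })
  out <- do.call(rbind, pts)
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  colnames(out) <- c("x", "y")
  out
}

# Scott's rule bandwidth for a 2-D Gaussian KDE, with a floor so degenerate
# point sets still yield a proper density
.scottBandwidth <- function(points, floor = 0.005) {
  n <- nrow(points)
  h <- apply(points, 2, stats::sd) * n^(-1 / 6)
  pmax(h, floor)
}

#' Estimate a feature density map
#'
#' Gaussian kernel density estimate of pooled normalized feature positions,
#' evaluated at the centers of a `gridResolution` x `gridResolution` grid
#' over the unit square and normalized to integrate to one. The bandwidth
#' defaults to Scott's rule per axis. The estimate is computed by linear
#' binning + FFT convolution ([KernSmooth::bkde2D]), which is deterministic
#' given points and bandwidth.
#'
#' @param points two-column matrix of normalized (x, y) positions (>= 2 rows).
#' @param gridResolution grid size per axis (default 128).
#' @param bandwidth optional numeric length-1/2 bandwidth (frame units);
#'   default Scott's rule.
#' @param level scale level recorded in the result (default NA).
#' @param nImages number of source images recorded in the result.
#' @return a [FeatureDensityMap-class].
#' @export
estimateDensity <- function(points, gridResolution = 128L, bandwidth = NULL,
                            level = NA_integer_, nImages = NA_integer_) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("insufficient data: at least 2 points are required for a density estimate")
  R <- as.integer(gridResolution)
  if (is.null(bandwidth)) bandwidth <- .scottBandwidth(points)
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, 2L)
  half <- 0.5 / R
  est <- KernSmooth::bkde2D(points, bandwidth = bandwidth,
                            gridsize = c(R, R),
                            range.x = list(c(half, 1 - half), c(half, 1 - half)))
  grid <- est$fhat
  grid[grid < 0] <- 0
  cell <- 1 / R^2
  s <- sum(grid) * cell
  if (s <= 0) stop("degenerate density: all mass fell outside the unit square")
  grid <- grid / s
  new("FeatureDensityMap", level = as.integer(level), grid = grid,
      nImages = as.integer(nImages), bandwidth = as.numeric(bandwidth),
      modelPoints = matrix(numeric(0), 0, 2))
}

.asGrid <- function(x) {
  if (is(x, "FeatureDensityMap")) x@grid else as.matrix(x)
}

#' Similarity between two density maps
#'
#' Both indices are computed on the discretized grids after renormalizing
#' each to sum to one: the Bray-Curtis index \eqn{1 - \sum|p-q| / \sum(p+q)}
#' and \eqn{1 - JSD(p, q)} with the Jensen-Shannon divergence taken in
#' base-2 logarithm (so it is bounded by 1). Both are symmetric, lie in
#' [0, 1], and equal 1 iff the maps coincide on the grid.
#'
#' @param a,b [FeatureDensityMap-class] objects (or plain matrices) on
#'   identical grids.
#' @param method `"bray_curtis"` or `"one_minus_jsd"`.
#' @return similarity in [0, 1].
#' @export
mapSimilarity <- function(a, b, method = c("bray_curtis", "one_minus_jsd")) {
  method <- match.arg(method)
  p <- .asGrid(a); q <- .asGrid(b)
  if (!all(dim(p) == dim(q)))
    stop("density maps have mismatched grid resolutions")
  p <- p / sum(p); q <- q / sum(q)
  if (method == "bray_curtis") {
    1 - sum(abs(p - q)) / sum(p + q)
  } else {
    m <- (p + q) / 2
    kl <- function(u, v) { i <- u > 0; sum(u[i] * log2(u[i] / v[i])) }
    1 - (0.5 * kl(p, m) + 0.5 * kl(q, m))
  }
}

#' Convergence of the density map as images accumulate
#'
#' Starting from the map estimated on the first `startN` images of the
#' stream, adds one image at a time and records the similarity between the
#' previous and the updated map under both indices. The KDE bandwidth is
#' fixed at the Scott's-rule value of the initial `startN`-image pool so
#' successive maps differ only through the accumulated data.
#'
#' @param stream ordered list of images (matrices) or of per-image feature
#'   data.frames from [extractFeatures]; length must exceed `startN`.
#' @param level scale level whose features are pooled.
#' @param startN size of the initial pool (default 25).
#' @param gridResolution KDE grid size (default 128).
#' @param nLevels pyramid depth used when images are given raw.
#' @return data.frame with columns `n` (images accumulated after the
#'   update), `bray_curtis` and `one_minus_jsd`.
#' @export
convergenceCurve <- function(stream, level, startN = 25L, gridResolution = 128L,
                             nLevels = 10L) {
  if (length(stream) <= startN)
    stop("stream must contain more than startN images")
  feats <- lapply(stream, function(s) {
    if (is.data.frame(s)) s else extractFeatures(s, nLevels = nLevels)
  })
  pts <- lapply(feats, accumulateFeatures, level = level)
  pooled <- do.call(rbind, pts[seq_len(startN)])
  if (nrow(pooled) < 2L)
    stop("initial pool has fewer than 2 feature points at this level")
  bw <- .scottBandwidth(pooled)
  prev <- estimateDensity(pooled, gridResolution, bandwidth = bw,
                          level = level, nImages = startN)
  out <- vector("list", length(stream) - startN)
  for (n in (startN + 1L):length(stream)) {
    pooled <- rbind(pooled, pts[[n]])
    cur <- estimateDensity(pooled, gridResolution, bandwidth = bw,
                           level = level, nImages = n)
    out[[n - startN]] <- data.frame(
      n = n,
      bray_curtis = mapSimilarity(prev, cur, "bray_curtis"),
      one_minus_jsd = mapSimilarity(prev, cur, "one_minus_jsd"))
    prev <- cur
  }
  do.call(rbind, out)
}

#' Select model points from a density map
#'
#' Finds the strict local maxima (8-neighborhood) of the density grid and
#' retains those whose value is at least `ratio` times the global maximum
#' (closed threshold); the global maximum cell is always included. The
#' selected points, in normalized frame coordinates, are stored in the map's
#' `modelPoints` slot.
#'
#' @param map a [FeatureDensityMap-class].
#' @param ratio fraction of the global maximum (default 0.7).
#' @return the map with `modelPoints` filled (two-column matrix, ordered by
#'   decreasing density value).
#' @export
selectModelPoints <- function(map, ratio = 0.7) {
  stopifnot(is(map, "FeatureDensityMap"), ratio > 0, ratio <= 1)
  G <- map@grid
  nx <- nrow(G); ny <- ncol(G)
  if (diff(range(G)) <= 0)
    stop("degenerate density map: grid is constant, no local maximum exists")
  shift <- function(dx, dy) {
    out <- matrix(-Inf, nx, ny)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    out[xs, ys] <- G[xs - dx, ys - dy]
    out
  }
  sh <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  isMax <- Reduce(`&`, lapply(sh, function(s) G > shift(s[1], s[2])))
  gmax <- max(G)
  cells <- which(isMax & G >= ratio * gmax, arr.ind = TRUE)
  top <- which(G == gmax, arr.ind = TRUE)[1, , drop = FALSE]
  if (!nrow(cells) || !any(cells[, 1] == top[1] & cells[, 2] == top[2]))
    cells <- rbind(top, cells)
  ord <- order(G[cells], decreasing = TRUE)
  cells <- cells[ord, , drop = FALSE]
  pts <- cbind(x = (cells[, 1] - 0.5) / nx, y = (cells[, 2] - 0.5) / ny)
  map@modelPoints <- pts
  map
}
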