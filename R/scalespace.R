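#' Build the Gaussian scale-space pyramid
#'
#' Constructs `nLevels` layers with scale schedule \eqn{\sigma_k =
#' \sqrt{2^{k-1}}} (Gaussian standard deviation, native pixels), halving the
#' working grid every two levels. Smoothing is incremental: each level is
#' obtained from the previous one by convolving with the Gaussian increment
#' needed to reach the target scale on the current grid, and downsampling is
#' factor-2 area averaging applied after smoothing. The scale-normalized
#' Laplacian \eqn{t (L_{xx} + L_{yy})}, \eqn{t = \sigma_k^2}, is computed for
#' every level with central finite differences (corrected for the grid
#' spacing) and stored alongside the smoothed image.
#'
#' @param image numeric matrix `[x, y]` (or `[x, y, 3]` RGB array, converted
#'   to luminance); smallest side must be at least 25 px.
#' @param nLevels number of pyramid layers (default 10).
#' @return a [ScaleSpacePyramid-class] object.
#' @examples
#' img <- matrix(runif(50 * 50), 50)
#' pyr <- buildPyramid(img, nLevels = 4)
#' scaleSigma(pyr)
#' @export
buildPyramid <- function(image, nLevels = 10L) {
  image <- toLuminance(image)
  if (min(dim(image)) < 25L)
    stop("image too small: smallest side must be >= 25 px (the patch size)")
  if (nLevels < 1L) stop("nLevels must be >= 1")
  nLevels <- as.integer(nLevels)
  cur <- image
  g <- 1L
  sOnGrid <- 0
  levels <- vector("list", nLevels)
  for (k in seq_len(nLevels)) {
    gk <- 2L^((k - 1L) %/% 2L)
    sigma <- sqrt(2^(k - 1))
    # smooth to the target scale on the current (finer) grid, then halve:
    # area averaging comes after smoothing, so the subsampled signal is
    # already band-limited
    inc <- sqrt(max((sigma / g)^2 - sOnGrid^2, 0))
    cur <- gaussianSmooth(cur, inc)
    sOnGrid <- sigma / g
    if (gk > g) {
      cur <- downsample2(cur)
      sOnGrid <- sOnGrid / 2
      g <- gk
    }
    target <- sigma / g
    # native second derivative = grid difference / g^2; t = sigma^2
    lap <- target^2 * (.d2X4(cur) + .d2Y4(cur))
    levels[[k]] <- new("ScaleLevel", index = k, sigma = sigma,
                       gridDownsample = as.integer(g), smoothed = cur,
                       laplacian = lap)
  }
  new("ScaleSpacePyramid", levels = levels,
      width = nrow(image), height = ncol(image))
}

#' @describeIn buildPyramid scale-normalized Laplacian map of one level.
#' @param x a [ScaleLevel-class] (or [ScaleSpacePyramid-class], returning a
#'   list of maps).
#' @param ... unused.
#' @export
setMethod("laplacianResponse", "ScaleLevel", function(x, ...) x@laplacian)

#' @export
setMethod("laplacianResponse", "ScaleSpacePyramid", function(x, ...)
  lapply(x@levels, function(l) l@laplacian))

#' Detect blob extrema at one pyramid level
#'
#' Finds spatial extrema of the scale-normalized Laplacian on the level's
#' grid (8-neighborhood). Saddle/edge responses are removed by the Hessian
#' definiteness test \eqn{\lambda_1 \lambda_2 > 0} (dark blobs have a
#' positive-definite Hessian of L, bright blobs negative-definite); plateaus
#' of equal extremal values contribute their centroid as a single point;
#' extrema within 1 px of the grid border are discarded. Coordinates are
#' mapped back to native resolution.
#'
#' @param level a [ScaleLevel-class].
#' @param borderMargin grid pixels to discard at the border (default 1).
#' @param minResponse contrast threshold on the normalized response
#'   (default 0.02 for intensities in [0, 1]): extrema weaker than this are
#'   treated as noise and dropped, improving repeatability of the detected
#'   points across images. Set to 0 to keep every extremum.
#' @return data.frame with columns `x`, `y` (native 0-based pixel-center
#'   coordinates), `level`, `sigma`, `response` (|normalized Laplacian| at
#'   the extremum, > 0) and `polarity` ("dark" or "bright").
#' @export
detectExtrema <- function(level, borderMargin = 1L, minResponse = 0.02) {
  stopifnot(is(level, "ScaleLevel"))
  L <- level@laplacian
  nx <- nrow(L); ny <- ncol(L)
  empty <- data.frame(x = numeric(0), y = numeric(0), level = integer(0),
                      sigma = numeric(0), response = numeric(0),
                      polarity = character(0), stringsAsFactors = FALSE)
  if (nx < 3L || ny < 3L) return(empty)
  sh <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  nb <- lapply(sh, function(s) .shiftReflect(L, s[1], s[2]))
  weakMax <- Reduce(`&`, lapply(nb, function(n) L >= n))
  weakMin <- Reduce(`&`, lapply(nb, function(n) L <= n))
  strict <- Reduce(`&`, lapply(nb, function(n) L != n))
  rng <- diff(range(level@smoothed))
  eps <- max(1e-12, 1e-9 * rng)
  thr <- max(eps, minResponse)
  interior <- matrix(FALSE, nx, ny)
  m <- borderMargin
  interior[(1L + m):(nx - m), (1L + m):(ny - m)] <- TRUE
  cand <- (weakMax | weakMin) & interior & (abs(L) > thr)
  if (!any(cand)) return(empty)

  # split strict single-cell extrema from plateaus
  strictCells <- which(cand & strict, arr.ind = TRUE)
  plateau <- cand & !strict
  ctr <- NULL
  if (any(plateau)) {
    lab <- EBImage::bwlabel(EBImage::Image(plateau * 1))
    lab <- matrix(EBImage::imageData(lab), nx, ny)
    for (id in setdiff(unique(as.vector(lab)), 0)) {
      cells <- which(lab == id, arr.ind = TRUE)
      v <- L[cells]
      if (diff(range(v)) > eps) next  # not a constant plateau: ambiguous, skip
      ctr <- rbind(ctr, c(mean(cells[, 1]), mean(cells[, 2])))
    }
  }
  ij <- rbind(if (nrow(strictCells)) cbind(strictCells[, 1], strictCells[, 2]),
              ctr)
  if (is.null(ij) || !nrow(ij)) return(empty)

  # Hessian definiteness at the (rounded) cell
  d2x <- .d2X(level@smoothed); d2y <- .d2Y(level@smoothed)
  dxy <- .dXY(level@smoothed)
  ri <- pmin(pmax(round(ij[, 1]), 1L), nx)
  rj <- pmin(pmax(round(ij[, 2]), 1L), ny)
  idx <- cbind(ri, rj)
  detH <- d2x[idx] * d2y[idx] - dxy[idx]^2
  keep <- detH > 0
  ij <- ij[keep, , drop = FALSE]; idx <- idx[keep, , drop = FALSE]
  if (!nrow(ij)) return(empty)
  g <- level@gridDownsample
  lv <- L[idx]
  data.frame(x = (ij[, 1] - 1) * g + (g - 1) / 2,
             y = (ij[, 2] - 1) * g + (g - 1) / 2,
             level = level@index, sigma = level@sigma,
             response = abs(lv),
             polarity = ifelse(lv > 0, "dark", "bright"),
             stringsAsFactors = FALSE)
}

#' Link blob extrema across adjacent scales
#'
#' Points detected at adjacent pyramid levels that lie within the linking
#' radius of each other (2 sigma of the coarser level, native pixels) and
#' share blob polarity are chained; each chain is represented by its single
#' strongest-response member. Unchained points pass through unchanged.
#'
#' @param points either a single data.frame as returned by [detectExtrema]
#'   (rows from any mix of levels) or a list of such data.frames.
#' @param radiusFactor multiple of the coarser sigma used as linking radius
#'   (default 2).
#' @return a flat data.frame of surviving feature points.
#' @export
linkScales <- function(points, radiusFactor = 2) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  if (is.null(points) || !nrow(points)) return(points)
  n <- nrow(points)
  edges <- list()
  lv <- sort(unique(points$level))
  for (k in lv) {
    if (!((k + 1L) %in% lv)) next
    a <- which(points$level == k)
    b <- which(points$level == k + 1L)
    if (!length(a) || !length(b)) next
    r <- radiusFactor * sqrt(2^k)  # sigma of the coarser level k+1
    # sweep over x-sorted candidates instead of a full distance matrix
    ord <- a[order(points$x[a])]
    xs <- points$x[ord]
    lo <- findInterval(points$x[b] - r, xs) + 1L
    hi <- findInterval(points$x[b] + r, xs)
    for (jj in seq_along(b)) {
      if (lo[jj] > hi[jj]) next
      cand <- ord[lo[jj]:hi[jj]]
      j <- b[jj]
      d2 <- (points$x[cand] - points$x[j])^2 + (points$y[cand] - points$y[j])^2
      cand <- cand[d2 <= r^2 & points$polarity[cand] == points$polarity[j]]
      if (length(cand))
        edges[[length(edges) + 1L]] <- cbind(cand, j)
    }
  }
  # union-find over the chain edges (flat loops: no closure copies)
  parent <- seq_len(n)
  if (length(edges)) {
    E <- do.call(rbind, edges)
    for (e in seq_len(nrow(E))) {
      i <- E[e, 1L]
      while (parent[i] != i) i <- parent[i]
      j <- E[e, 2L]
      while (parent[j] != j) j <- parent[j]
      if (i != j) parent[i] <- j
    }
  }
  root <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    while (parent[j] != j) j <- parent[j]
    root[i] <- j
  }
  keep <- vapply(split(seq_len(n), root), function(ix)
    ix[which.max(points$response[ix])], integer(1))
  out <- points[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract linked scale-space features from an image
#'
#' Convenience wrapper: builds the pyramid, detects blob extrema at every
#' level and links them across scales.
#'
#' @param image numeric image matrix, or an already-built
#'   [ScaleSpacePyramid-class].
#' @param nLevels pyramid depth (default 10); ignored if a pyramid is given.
#' @param radiusFactor see [linkScales].
#' @return data.frame of linked feature points (see [detectExtrema]).
#' @export
extractFeatures <- function(image, nLevels = 10L, radiusFactor = 2) {
  pyr <- if (is(image, "ScaleSpacePyramid")) image else buildPyramid(image, nLevels)
  out <- linkScales(lapply(scaleLevels(pyr), detectExtrema),
                    radiusFactor = radiusFactor)
  attr(out, "imageWidth") <- pyr@width
  attr(out, "imageHeight") <- pyr@height
  out
}
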