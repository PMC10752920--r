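# cell boundaries: split `size` pixels into `cells` nearly equal runs
.cellEdges <- function(size, cells) round(size / cells * (0:cells))

# constant index structures for a given patch geometry, cached: reflected
# +/-1 shift indices and the per-pixel descriptor-component offset
.hogCache <- new.env(parent = emptyenv())
.hogGeometry <- function(size, cells, bins) {
  key <- paste(size, cells, bins)
  g <- .hogCache[[key]]
  if (is.null(g)) {
    up <- c(1L, seq_len(size - 1L))   # index i-1, edge-inclusive reflection
    dn <- c(seq.int(2L, size), size)  # index i+1, edge-inclusive reflection
    edges <- .cellEdges(size, cells)
    cellIdx <- findInterval(seq_len(size), edges[-1] + 0.5) + 1L
    cx <- matrix(cellIdx, size, size)
    cy <- matrix(cellIdx, size, size, byrow = TRUE)
    cellOff <- ((cy - 1L) * cells + (cx - 1L)) * bins
    # pixel-to-cell indicator for batched accumulation
    C <- matrix(0, size^2, cells^2)
    C[cbind(seq_len(size^2), as.vector(cellOff) / bins + 1L)] <- 1
    g <- list(up = up, dn = dn, cellOff = cellOff, D = cells^2 * bins,
              C = C)
    .hogCache[[key]] <- g
  }
  g
}

# map gradient (gx, gy) to unsigned-orientation bin in 1..bins over [0, pi)
.orientationBin <- function(gx, gy, bins) {
  ang <- atan2(gy, gx) %% pi
  b <- floor(ang / pi * bins) + 1L
  b[b > bins] <- bins
  b
}

#' Extract a square patch centered at a point
#'
#' Returns a `size` x `size` patch of the image centered at (x, y) (0-based
#' pixel-center coordinates, rounded to the nearest pixel); pixels falling
#' outside the image are filled by symmetric reflection.
#'
#' @param image numeric image matrix.
#' @param center numeric length-2, (x, y); must lie inside the image.
#' @param size odd patch side (default 25).
#' @return numeric `size` x `size` matrix.
#' @export
extractPatch <- function(image, center, size = 25L) {
  stopifnot(size %% 2L == 1L)
  nx <- nrow(image); ny <- ncol(image)
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1)
    stop("patch center lies outside the image")
  r <- (size - 1L) %/% 2L
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  ix <- refl(round(cx) + 1L + seq(-r, r), nx)
  iy <- refl(round(cy) + 1L + seq(-r, r), ny)
  image[ix, iy, drop = FALSE]
}

#' HOG descriptor of a patch
#'
#' Partitions the patch into a `cells` x `cells` grid (9 cells by default)
#' and computes per cell a histogram of unsigned gradient orientation
#' ([0, 180) degrees, `bins` bins) weighted by gradient magnitude; gradients
#' are central differences with reflected patch borders. The concatenation
#' (cells in row-major order over (y, x), bins ascending) is L2-normalized
#' with epsilon 1e-6, yielding `cells^2 * bins` = 144 components at the
#' defaults.
#'
#' @param patch numeric square matrix, 25 x 25 at the default configuration.
#' @param cells cells per axis (default 3).
#' @param bins orientation bins per cell (default 16).
#' @return numeric vector of length `cells^2 * bins`.
#' @export
hogDescriptor <- function(patch, cells = 3L, bins = 16L) {
  size <- nrow(patch)
  if (ncol(patch) != size)
    stop("patch must be square")
  g <- .hogGeometry(size, cells, bins)
  gx <- (patch[g$dn, ] - patch[g$up, ]) / 2
  gy <- (patch[, g$dn] - patch[, g$up]) / 2
  mag <- sqrt(gx^2 + gy^2)
  bin <- .orientationBin(gx, gy, bins)
  comp <- g$cellOff + bin
  acc <- rowsum(as.vector(mag), as.vector(comp))
  out <- numeric(g$D)
  out[as.integer(rownames(acc))] <- acc
  out / sqrt(sum(out^2) + 1e-6^2)
}

# HOG descriptor of the size x size patch centered at `center` (0-based),
# with gradients computed in full image context (one pixel beyond the
# patch, reflected at image borders) — exactly matching the dense
# detection path
.hogAt <- function(image, center, size = 25L, cells = 3L, bins = 16L) {
  g <- .hogGeometry(size, cells, bins)
  r <- (size - 1L) %/% 2L + 1L  # one-pixel context margin
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  ix <- refl(round(center[1]) + 1L + seq(-r, r), nrow(image))
  iy <- refl(round(center[2]) + 1L + seq(-r, r), ncol(image))
  p <- image[ix, iy, drop = FALSE]
  n2 <- size + 2L
  core <- 2:(n2 - 1L)
  gx <- (p[3:n2, core] - p[1:(n2 - 2L), core]) / 2
  gy <- (p[core, 3:n2] - p[core, 1:(n2 - 2L)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  bin <- .orientationBin(gx, gy, bins)
  acc <- rowsum(as.vector(mag), as.vector(g$cellOff + bin))
  out <- numeric(g$D)
  out[as.integer(rownames(acc))] <- acc
  out / sqrt(sum(out^2) + 1e-6^2)
}

# batched .hogAt: descriptors for many patch centers of one image at once
# (identical numerics, vectorized across patches)
.hogBatch <- function(image, centers, size = 25L, cells = 3L, bins = 16L) {
  g <- .hogGeometry(size, cells, bins)
  n <- nrow(centers)
  if (!n) return(matrix(numeric(0), 0, g$D))
  r <- (size - 1L) %/% 2L + 1L
  n2 <- size + 2L
  refl <- function(i, lim) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > lim, 2L * lim + 1L - i, i)
  }
  IX <- refl(outer(seq(-r, r), round(centers[, 1]) + 1L, "+"), nrow(image))
  IY <- refl(outer(seq(-r, r), round(centers[, 2]) + 1L, "+"), ncol(image))
  # window array A[n2, n2, n]
  A <- array(0, c(n2, n2, n))
  for (p in seq_len(n))
    A[, , p] <- image[IX[, p], IY[, p]]
  core <- 2:(n2 - 1L)
  gx <- (A[3:n2, core, , drop = FALSE] - A[1:(n2 - 2L), core, , drop = FALSE]) / 2
  gy <- (A[core, 3:n2, , drop = FALSE] - A[core, 1:(n2 - 2L), , drop = FALSE]) / 2
  ss <- size * size
  mag <- matrix(sqrt(gx^2 + gy^2), ss, n)
  bin <- matrix(.orientationBin(gx, gy, bins), ss, n)
  V <- matrix(0, g$D, n)
  for (b in seq_len(bins))
    V[seq.int(b, g$D, by = bins), ] <- crossprod(g$C, mag * (bin == b))
  t(V / rep(sqrt(colSums(V^2) + 1e-6^2), each = g$D))
}

#' Build a labeled descriptor table for one model scale
#'
#' For every positive image, one descriptor is extracted per model point of
#' the level (label 1), with the patch taken on the pyramid level's grid
#' (the smoothed, downsampled image) at the model point's normalized
#' position. Negative descriptors (label 0) are sampled at uniformly random
#' positions of the negative images' same pyramid level, with the total
#' count matched to the number of positive rows (distributed evenly across
#' negative images); sampling is seeded and reproducible.
#'
#' @param positives list of face image matrices.
#' @param negatives list of non-face image matrices.
#' @param level scale level.
#' @param modelPointsAtLevel two-column matrix of normalized model points.
#' @param seed integer seed for negative sampling.
#' @param patchSize patch side (default 25).
#' @param nNegative optional total negative count (default: equals positives).
#' @return data.frame with columns `f1..f144`, `label` (0/1), `image`,
#'   `x`, `y` (grid coordinates of the patch center) and `level`.
#' @export
buildTrainingSet <- function(positives, negatives, level, modelPointsAtLevel,
                             seed = 1L, patchSize = 25L, nNegative = NULL) {
  mp <- as.matrix(modelPointsAtLevel)
  if (!nrow(mp)) stop("model is incomplete: no model points at this level")
  levelImage <- function(img) {
    smoothedImage(scaleLevels(buildPyramid(img, nLevels = level))[[level]])
  }
  descRow <- function(li, ctr) .hogAt(li, ctr, patchSize)
  pos <- vector("list", length(positives) * nrow(mp))
  meta <- vector("list", length(pos))
  r <- 0L
  for (i in seq_along(positives)) {
    li <- levelImage(positives[[i]])
    nx <- nrow(li); ny <- ncol(li)
    for (j in seq_len(nrow(mp))) {
      ctr <- c(min(max(mp[j, 1] * nx - 0.5, 0), nx - 1),
               min(max(mp[j, 2] * ny - 0.5, 0), ny - 1))
      r <- r + 1L
      pos[[r]] <- descRow(li, ctr)
      meta[[r]] <- c(i, ctr, 1L)
    }
  }
  nPos <- r
  if (is.null(nNegative)) nNegative <- nPos
  neg <- vector("list", nNegative)
  nmeta <- vector("list", nNegative)
  set.seed(as.integer(seed))
  imgOf <- rep(seq_along(negatives), length.out = nNegative)
  r <- 0L
  for (i in seq_along(negatives)) {
    cnt <- sum(imgOf == i)
    if (!cnt) next
    li <- levelImage(negatives[[i]])
    nx <- nrow(li); ny <- ncol(li)
    for (j in seq_len(cnt)) {
      ctr <- c(stats::runif(1, 0, nx - 1), stats::runif(1, 0, ny - 1))
      r <- r + 1L
      neg[[r]] <- descRow(li, ctr)
      nmeta[[r]] <- c(-i, ctr, 0L)
    }
  }
  X <- do.call(rbind, c(pos[seq_len(nPos)], neg[seq_len(r)]))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  M <- do.call(rbind, c(meta[seq_len(nPos)], nmeta[seq_len(r)]))
  out <- data.frame(X)
  out$label <- as.integer(M[, 4])
  out$image <- as.integer(M[, 1])
  out$x <- M[, 2]
  out$y <- M[, 3]
  out$level <- as.integer(level)
  out
}

#' Train the binary patch classifier
#'
#' Fits a linear max-margin separator (SVM, cost C = 1 by default) on a
#' labeled descriptor table and stores it as an explicit weight vector +
#' bias oriented so that a positive decision value means label 1.
#'
#' @param table data.frame from [buildTrainingSet] (feature columns
#'   `f1..fD` plus `label`), or any data.frame with such columns.
#' @param seed integer seed (recorded; training itself is deterministic).
#' @param cost SVM cost parameter (default 1).
#' @return a [PatchClassifier-class].
#' @export
trainClassifier <- function(table, seed = 1L, cost = 1) {
  fc <- grep("^f[0-9]+$", names(table), value = TRUE)
  X <- as.matrix(table[, fc])
  y <- table$label
  if (length(unique(y)) < 2L)
    stop("degenerate training set: both classes must be present")
  set.seed(as.integer(seed))
  m <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "linear",
                  cost = cost, scale = FALSE)
  w <- unname(drop(t(m$coefs) %*% m$SV))
  b <- -m$rho
  # orient so that score > 0 <=> label 1
  pred <- as.integer(as.character(stats::predict(m, X)))
  sc <- drop(X %*% w) + b
  if (mean((sc > 0) == (pred == 1L)) < 0.5) { w <- -w; b <- -b }
  lev <- if ("level" %in% names(table)) table$level[1] else NA_integer_
  new("PatchClassifier", level = as.integer(lev), weights = w, bias = b,
      meta = list(nPos = sum(y == 1), nNeg = sum(y == 0),
                  seed = as.integer(seed), cost = cost))
}

#' Classify patch descriptors
#'
#' Hard binary classification of descriptor rows: returns 1 where the linear
#' decision value is positive, 0 otherwise.
#'
#' @param classifier a [PatchClassifier-class].
#' @param descriptors numeric vector (one descriptor) or matrix (one row per
#'   descriptor).
#' @return integer vector of 0/1 labels.
#' @export
classifyDescriptors <- function(classifier, descriptors) {
  if (is.null(dim(descriptors))) descriptors <- matrix(descriptors, nrow = 1)
  as.integer(drop(descriptors %*% classifier@weights) + classifier@bias > 0)
}
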