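# on-grid smoothing applied to a working image before patch evaluation,
# matching the residual smoothing of the training pyramid level
.levelGridSigma <- function(k) sqrt(2^(k - 1)) / 2^((k - 1) %/% 2)

#' Resize-factor schedule of the detection cascade
#'
#' Geometric sequence of working-image resize factors stepping by sqrt(2),
#' covering face-size hypotheses from the whole image spanning
#' `referenceFacePx` up to faces of `referenceFacePx` at native resolution
#' (factor 1). Factors whose working image would fall below the patch size
#' are dropped. Returned ascending, i.e. coarsest hypothesis (smallest
#' working image) first.
#'
#' @param imageSize numeric length-2 (width, height) in pixels.
#' @param model optional [FaceModel-class] supplying `referenceFacePx` and
#'   `patchSize`.
#' @param step factor ratio between consecutive hypotheses (default sqrt(2)).
#' @param referenceFacePx,patchSize used when no model is given.
#' @return numeric vector of resize factors (possibly empty).
#' @export
resizeSchedule <- function(imageSize, model = NULL, step = sqrt(2),
                           referenceFacePx = 32L, patchSize = 25L) {
  if (!is.null(model)) {
    referenceFacePx <- model@referenceFacePx
    patchSize <- model@patchSize
  }
  S <- min(imageSize)
  if (S < patchSize) return(numeric(0))
  fmin <- max(patchSize, referenceFacePx / step) / S
  f <- 1
  out <- numeric(0)
  while (f >= fmin * (1 - 1e-9)) {
    out <- c(out, f)
    f <- f / step
  }
  rev(out)
}

# dense linear-SVM score map over all fully-contained patch centers.
# Returns a matrix whose [a, b] entry is the decision value for the patch
# centered at working-image pixel (a + r, b + r), 1-based, r = (size-1)/2.
.denseScoreMap <- function(img, classifier, patchSize = 25L, cells = 3L,
                           bins = 16L) {
  nx <- nrow(img); ny <- ncol(img)
  r <- (patchSize - 1L) %/% 2L
  if (nx < patchSize || ny < patchSize) return(NULL)
  gx <- .gradX(img); gy <- .gradY(img)
  mag <- sqrt(gx^2 + gy^2)
  bin <- .orientationBin(gx, gy, bins)
  edges <- .cellEdges(patchSize, cells)
  vx <- (r + 1L):(nx - r); vy <- (r + 1L):(ny - r)
  nvx <- length(vx); nvy <- length(vy)
  ints <- vector("list", bins)
  for (b in seq_len(bins)) {
    B <- mag * (bin == b)
    S <- matrix(0, nx + 1L, ny + 1L)
    S[-1, -1] <- t(apply(apply(B, 2, cumsum), 1, cumsum))
    ints[[b]] <- S
  }
  w <- classifier@weights
  D <- cells^2 * bins
  X <- matrix(0, nvx * nvy, D)
  for (cy in seq_len(cells)) for (cx in seq_len(cells)) {
    u0 <- edges[cx] + 1L - (r + 1L); u1 <- edges[cx + 1L] - (r + 1L)
    v0 <- edges[cy] + 1L - (r + 1L); v1 <- edges[cy + 1L] - (r + 1L)
    ra <- vx + u0; rb <- vx + u1
    ca <- vy + v0; cb <- vy + v1
    for (b in seq_len(bins)) {
      S <- ints[[b]]
      comp <- S[rb + 1L, cb + 1L, drop = FALSE] -
              S[ra, cb + 1L, drop = FALSE] -
              S[rb + 1L, ca, drop = FALSE] + S[ra, ca, drop = FALSE]
      X[, ((cy - 1L) * cells + (cx - 1L)) * bins + b] <- as.vector(comp)
    }
  }
  nrm <- sqrt(rowSums(X^2) + 1e-6^2)
  sc <- drop(X %*% w) / nrm + classifier@bias
  matrix(sc, nvx, nvy)
}

# votes of a scale's model points over every working-image pixel.
# scoreMap as from .denseScoreMap; offsets are integer (dx, dy) per model
# point. Returns positive-vote and evaluable-patch counts per pixel: a
# patch placed outside the working image is not evaluable (a face near
# the border is judged on the patches that fit, not penalized for the
# rest).
.voteMap <- function(scoreMap, nx, ny, offsets, r) {
  pos <- scoreMap > 0
  votes <- matrix(0L, nx, ny)
  avail <- matrix(0L, nx, ny)
  for (m in seq_len(nrow(offsets))) {
    ox <- offsets[m, 1]; oy <- offsets[m, 2]
    # patch center for candidate (i, j) is (i + ox, j + oy); valid when
    # r+1 <= i+ox <= nx-r
    i0 <- max(1L, r + 1L - ox); i1 <- min(nx, nx - r - ox)
    j0 <- max(1L, r + 1L - oy); j1 <- min(ny, ny - r - oy)
    if (i0 > i1 || j0 > j1) next
    blk <- pos[(i0 + ox - r):(i1 + ox - r), (j0 + oy - r):(j1 + oy - r),
               drop = FALSE]
    votes[i0:i1, j0:j1] <- votes[i0:i1, j0:j1] + blk
    avail[i0:i1, j0:j1] <- avail[i0:i1, j0:j1] + 1L
  }
  list(votes = votes, avail = avail)
}

#' Run the coarse-to-fine face detection cascade
#'
#' For every resize factor of the schedule the working image is evaluated
#' at the model's coarsest scale: at each pixel (stride 1 by default),
#' 25 x 25 HOG patches are placed at the scale's model-point offsets inside
#' the hypothesized face frame (`referenceFacePx` pixels) and classified;
#' the pixel survives when at least `voteFraction` of the patches classify
#' positive. Survivors are re-evaluated at each finer model scale on a
#' working image enlarged by the inter-stage factor, with coordinates and
#' model-point offsets scaled accordingly. A candidate passing all scales
#' becomes a detection: a square of side `referenceFacePx / factor`
#' centered at the candidate, with binary score 1.
#'
#' Each working image is pre-smoothed with the residual on-grid sigma of
#' the corresponding training pyramid level, so detection patches see the
#' same blur the classifier was trained on.
#'
#' @param image numeric image matrix (or RGB array).
#' @param model a trained [FaceModel-class].
#' @param stride coarse-stage pixel stride (default 1, every pixel).
#' @param voteFraction fraction of a scale's model-point patches that must
#'   classify positive (default 0.5); either a scalar or one value per
#'   model scale (coarse to fine). The coarsest stage requires a strict
#'   majority (votes strictly above the fraction), the confirmation stages
#'   at least the fraction.
#' @param merge logical; merge overlapping detections ([mergeDetections]).
#'   Off by default.
#' @param mergeIoU IoU threshold used when `merge = TRUE` (default 0.3).
#' @param stageScaleBase "sigma" (default): inter-stage coordinate factor
#'   2^((k_coarse - k_fine)/2), following the sigma schedule; "grid": the
#'   pyramid grid ratio 2^(floor/floor), matching training grid sizes.
#' @return data.frame of detections (`x`, `y`, `w`, `h` in native 0-based
#'   pixels, `score`, `level`, `factor`), with the per-stage survivor table
#'   in attribute `"candidates"`.
#' @export
detectFaces <- function(image, model, stride = 1L, voteFraction = 0.5,
                        merge = FALSE, mergeIoU = 0.3,
                        stageScaleBase = c("sigma", "grid")) {
  stopifnot(is(model, "FaceModel"))
  stageScaleBase <- match.arg(stageScaleBase)
  image <- toLuminance(image)
  nx0 <- nrow(image); ny0 <- ncol(image)
  ref <- model@referenceFacePx
  ps <- model@patchSize
  r <- (ps - 1L) %/% 2L
  scales <- model@scales
  voteFraction <- rep_len(voteFraction, length(scales))
  names(voteFraction) <- as.character(scales)
  kc <- scales[1]
  stageFactor <- function(kf) {
    if (stageScaleBase == "sigma") 2^((kc - kf) / 2)
    else 2^((kc - 1L) %/% 2L - (kf - 1L) %/% 2L)
  }
  sched <- resizeSchedule(c(nx0, ny0), model)
  det <- list(); cand <- list()
  for (f in sched) {
    w1 <- max(1L, round(nx0 * f)); h1 <- max(1L, round(ny0 * f))
    if (min(w1, h1) < ps) next
    work <- gaussianSmooth(resizeImage(image, w1, h1), .levelGridSigma(kc))
    clf <- model@classifiers[[as.character(kc)]]
    mp <- model@modelPoints[[as.character(kc)]]
    offs <- cbind(round((mp[, 1] - 0.5) * ref), round((mp[, 2] - 0.5) * ref))
    # reflection-pad so faces at the image border keep all their patches
    # evaluable (training patches reflect at borders the same way)
    pad <- r + max(abs(offs))
    sm <- .denseScoreMap(padReflect(work, pad), clf, ps)
    if (is.null(sm)) next
    vm <- .voteMap(sm, w1 + 2L * pad, h1 + 2L * pad, offs, r)
    votes <- vm$votes[pad + seq_len(w1), pad + seq_len(h1), drop = FALSE]
    # the coarse stage is the cascade's per-pixel gatekeeper: a bare tie of
    # its model-point patches is not evidence of a face, so it must clear a
    # strict majority (this also keeps its clutter firing rate low);
    # confirmation stages accept at least the voteFraction
    ok <- votes > 0 & votes > voteFraction[[1]] * nrow(mp)
    if (stride > 1L) {
      keepIdx <- matrix(FALSE, w1, h1)
      keepIdx[seq(1L, w1, stride), seq(1L, h1, stride)] <- TRUE
      ok <- ok & keepIdx
    }
    cells <- which(ok, arr.ind = TRUE)
    if (!nrow(cells)) next
    cand[[length(cand) + 1L]] <- data.frame(
      factor = f, stage = kc,
      cx = (cells[, 1] - 0.5) / f - 0.5, cy = (cells[, 2] - 0.5) / f - 0.5)
    survivors <- cells
    for (kf in scales[-1]) {
      if (!nrow(survivors)) break
      rs <- stageFactor(kf)
      w2 <- max(1L, round(nx0 * f * rs)); h2 <- max(1L, round(ny0 * f * rs))
      if (min(w2, h2) < ps) { survivors <- survivors[0, , drop = FALSE]; break }
      workF <- gaussianSmooth(resizeImage(image, w2, h2), .levelGridSigma(kf))
      clfF <- model@classifiers[[as.character(kf)]]
      mpF <- model@modelPoints[[as.character(kf)]]
      faceSz <- ref * rs
      padF <- as.integer(ceiling(max(abs(mpF - 0.5)) * faceSz)) + 1L
      workFP <- padReflect(workF, padF)
      nmp <- nrow(mpF)
      ns <- nrow(survivors)
      # all (candidate x model point) patch centers, scored in one batch
      c2x <- (survivors[, 1] - 0.5) * rs - 0.5
      c2y <- (survivors[, 2] - 0.5) * rs - 0.5
      ctrs <- cbind(rep(c2x, each = nmp) + (mpF[, 1] - 0.5) * faceSz + padF,
                    rep(c2y, each = nmp) + (mpF[, 2] - 0.5) * faceSz + padF)
      lab <- integer(nrow(ctrs))
      for (ch in split(seq_len(nrow(ctrs)),
                       (seq_len(nrow(ctrs)) - 1L) %/% 5000L))
        lab[ch] <- classifyDescriptors(clfF,
                                       .hogBatch(workFP, ctrs[ch, , drop = FALSE], ps))
      v <- rowsum(lab, rep(seq_len(ns), each = nmp))[, 1]
      keep <- v > 0L & v >= voteFraction[[as.character(kf)]] * nmp
      survivors <- survivors[keep, , drop = FALSE]
      if (nrow(survivors))
        cand[[length(cand) + 1L]] <- data.frame(
          factor = f, stage = kf,
          cx = (survivors[, 1] - 0.5) / f - 0.5,
          cy = (survivors[, 2] - 0.5) / f - 0.5)
    }
    if (nrow(survivors)) {
      side <- ref / f
      cx <- (survivors[, 1] - 0.5) / f - 0.5
      cy <- (survivors[, 2] - 0.5) / f - 0.5
      d <- data.frame(x = cx - side / 2, y = cy - side / 2,
                      w = side, h = side, score = 1L, level = kc, factor = f)
      # clip to image bounds; drop if clipping removes > 50% of the area
      x2 <- pmin(d$x + d$w, nx0); y2 <- pmin(d$y + d$h, ny0)
      d$x <- pmax(d$x, 0); d$y <- pmax(d$y, 0)
      a0 <- side^2
      d$w <- x2 - d$x; d$h <- y2 - d$y
      keep <- d$w > 0 & d$h > 0 & (d$w * d$h) >= 0.5 * a0
      det[[length(det) + 1L]] <- d[keep, , drop = FALSE]
    }
  }
  out <- if (length(det)) do.call(rbind, det) else
    data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
               score = integer(0), level = integer(0), factor = numeric(0))
  rownames(out) <- NULL
  if (merge) out <- mergeDetections(out, iouMerge = mergeIoU, enabled = TRUE)
  attr(out, "candidates") <- if (length(cand)) do.call(rbind, cand) else
    data.frame(factor = numeric(0), stage = integer(0), cx = numeric(0),
               cy = numeric(0))
  out
}

#' Merge overlapping detections
#'
#' Groups detections into connected components under the overlap relation
#' (pairwise IoU >= `iouMerge`, or intersection covering at least
#' `containMerge` of the smaller box, which links a re-detection of the
#' same face at the next cascade scale) and replaces each group by its
#' component-wise mean rectangle — the consensus of the stride-1 duplicate
#' windows a true face produces. Groups smaller than `minNeighbors` are
#' dropped as uncorroborated. Disabled (identity) by default, mirroring a
#' detector that reports raw cascade output including occasional double
#' detections.
#'
#' @param detections data.frame with `x`, `y`, `w`, `h` columns.
#' @param iouMerge IoU threshold (default 0.3).
#' @param containMerge intersection-over-smaller-area threshold (default
#'   0.6); set above 1 to disable containment linking.
#' @param minNeighbors minimum group size to keep (default 1: keep all).
#' @param enabled logical (default FALSE: return input unchanged).
#' @return data.frame of merged detections with a `members` column giving
#'   each group's size.
#' @export
mergeDetections <- function(detections, iouMerge = 0.3, containMerge = 0.6,
                            minNeighbors = 1L, enabled = FALSE) {
  if (!enabled || !nrow(detections)) return(detections)
  n <- nrow(detections)
  inter <- function(i, j) {
    iw <- max(0, min(detections$x[i] + detections$w[i],
                     detections$x[j] + detections$w[j]) -
                 max(detections$x[i], detections$x[j]))
    ih <- max(0, min(detections$y[i] + detections$h[i],
                     detections$y[j] + detections$h[j]) -
                 max(detections$y[i], detections$y[j]))
    iw * ih
  }
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ov <- inter(i, j) / min(detections$w[i] * detections$h[i],
                            detections$w[j] * detections$h[j])
    if (rectIoU(detections[i, ], detections[j, ]) >= iouMerge ||
        ov >= containMerge) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(x = mean(detections$x[ix]), y = mean(detections$y[ix]),
               w = mean(detections$w[ix]), h = mean(detections$h[ix]),
               score = 1L, level = detections$level[ix][1],
               factor = stats::median(detections$factor[ix]),
               members = length(ix))
  }))
  out <- out[out$members >= minNeighbors, , drop = FALSE]
  rownames(out) <- NULL
  out
}
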