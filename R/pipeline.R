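# positive descriptor rows for one pyramid-level image and a set of
# normalized model points (shared by buildTrainingSet and buildFaceModel)
.positiveRows <- function(levelImage, modelPts, patchSize) {
  nx <- nrow(levelImage); ny <- ncol(levelImage)
  t(apply(modelPts, 1, function(m) {
    ctr <- c(min(max(m[1] * nx - 0.5, 0), nx - 1),
             min(max(m[2] * ny - 0.5, 0), ny - 1))
    .hogAt(levelImage, ctr, patchSize)
  }))
}

#' Train a multi-scale face model end to end
#'
#' Runs the whole model-construction pipeline on a collection of aligned
#' face images: builds each image's scale-space pyramid once, extracts
#' linked blob features, pools them per requested level into a feature
#' density map, selects model points by the fraction-of-global-maximum
#' rule, assembles HOG descriptor training sets (positives at model
#' points, negatives at seeded random positions of the clutter images) and
#' trains one linear SVM patch classifier per level.
#'
#' @param positives list of aligned face image matrices.
#' @param negatives list of clutter image matrices.
#' @param levels integer vector of scale levels, coarse to fine
#'   (default c(7, 4), the fixation-guided choice).
#' @param gridResolution density-map grid (default 128).
#' @param ratio model-point selection threshold (default 0.7).
#' @param referenceFacePx face-frame size at the coarsest cascade stage
#'   (default 32).
#' @param patchSize patch side (default 25).
#' @param nLevels pyramid depth for feature extraction (default 10).
#' @param seed integer seed (negative sampling).
#' @return a [FaceModel-class]; the per-level density maps are kept in
#'   `provenance$densityMaps`.
#' @export
buildFaceModel <- function(positives, negatives, levels = c(7L, 4L),
                           gridResolution = 128L, ratio = 0.7,
                           referenceFacePx = 32L, patchSize = 25L,
                           nLevels = 10L, seed = 1L) {
  levels <- as.integer(levels)
  key <- as.character(levels)
  feats <- vector("list", length(positives))
  posLevelImgs <- lapply(levels, function(k) vector("list", length(positives)))
  names(posLevelImgs) <- key
  for (i in seq_along(positives)) {
    pyr <- buildPyramid(positives[[i]], nLevels = nLevels)
    feats[[i]] <- extractFeatures(pyr)
    for (k in key)
      posLevelImgs[[k]][[i]] <-
        smoothedImage(scaleLevels(pyr)[[as.integer(k)]])
  }
  negLevelImgs <- lapply(levels, function(k)
    lapply(negatives, function(img)
      smoothedImage(scaleLevels(buildPyramid(img, nLevels = k))[[k]])))
  names(negLevelImgs) <- key

  maps <- list(); mps <- list(); clfs <- list()
  for (k in levels) {
    ck <- as.character(k)
    pooled <- accumulateFeatures(feats, level = k)
    map <- selectModelPoints(
      estimateDensity(pooled, gridResolution, level = k,
                      nImages = length(positives)), ratio = ratio)
    mp <- modelPoints(map)
    pos <- do.call(rbind, lapply(posLevelImgs[[ck]], .positiveRows,
                                 modelPts = mp, patchSize = patchSize))
    nPos <- nrow(pos)
    set.seed(as.integer(seed) + k)
    negImgs <- negLevelImgs[[ck]]
    imgOf <- rep(seq_along(negImgs), length.out = nPos)
    neg <- matrix(0, nPos, ncol(pos))
    rix <- 0L
    for (i in seq_along(negImgs)) {
      cnt <- sum(imgOf == i)
      if (!cnt) next
      li <- negImgs[[i]]
      for (j in seq_len(cnt)) {
        ctr <- c(stats::runif(1, 0, nrow(li) - 1),
                 stats::runif(1, 0, ncol(li) - 1))
        rix <- rix + 1L
        neg[rix, ] <- .hogAt(li, ctr, patchSize)
      }
    }
    X <- rbind(pos, neg[seq_len(rix), , drop = FALSE])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    tab <- data.frame(X)
    tab$label <- rep(c(1L, 0L), c(nPos, rix))
    tab$level <- k
    maps[[ck]] <- map
    mps[[ck]] <- mp
    clfs[[ck]] <- trainClassifier(tab, seed = as.integer(seed) + k)
  }
  new("FaceModel", scales = levels, modelPoints = mps, classifiers = clfs,
      referenceFacePx = as.integer(referenceFacePx),
      patchSize = as.integer(patchSize),
      provenance = list(nPositives = length(positives),
                        nNegatives = length(negatives),
                        seed = as.integer(seed),
                        densityMaps = maps))
}
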