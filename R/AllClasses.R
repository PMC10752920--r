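#' Scale-space container classes
#'
#' `ScaleLevel` holds one layer of the Gaussian scale-space pyramid: the
#' smoothed image on its (possibly downsampled) grid and the scale-normalized
#' Laplacian response. `ScaleSpacePyramid` is the ordered list of levels built
#' from one source image.
#'
#' The scale schedule is \eqn{\sigma_k = \sqrt{2^{k-1}}} (pixels at native
#' resolution, Gaussian standard deviation) and the working grid is halved
#' every two levels, so \code{gridDownsample} is \eqn{2^{\lfloor (k-1)/2
#' \rfloor}}.
#'
#' Images throughout the package are numeric matrices indexed \code{[x, y]}
#' (the EBImage convention); pixel centers are 0-based, so array cell
#' \code{[i, j]} of a level with downsample factor \eqn{g} sits at native
#' coordinates \eqn{((i-1) g + (g-1)/2,\; (j-1) g + (g-1)/2)}.
#'
#' @slot index integer scale index k (1-based).
#' @slot sigma Gaussian standard deviation at native resolution.
#' @slot gridDownsample integer power of two.
#' @slot smoothed numeric matrix, the smoothed image on the level grid.
#' @slot laplacian numeric matrix, scale-normalized Laplacian (t = sigma^2).
#' @aliases ScaleLevel ScaleSpacePyramid
#' @name ScaleLevel-class
#' @exportClass ScaleLevel
setClass("ScaleLevel",
  representation(index = "integer", sigma = "numeric",
                 gridDownsample = "integer",
                 smoothed = "matrix", laplacian = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@index) != 1L || object@index < 1L)
      msg <- c(msg, "index must be a single positive integer")
    sig <- sqrt(2^(object@index - 1L))
    if (abs(object@sigma - sig) > 1e-9 * sig)
      msg <- c(msg, sprintf("sigma must equal sqrt(2^(k-1)) = %.6f", sig))
    g <- 2L^((object@index - 1L) %/% 2L)
    if (object@gridDownsample != g)
      msg <- c(msg, sprintf("gridDownsample must equal 2^floor((k-1)/2) = %d", g))
    if (length(msg)) msg else TRUE
  })

#' @name ScaleLevel-class
#' @exportClass ScaleSpacePyramid
setClass("ScaleSpacePyramid",
  representation(levels = "list", width = "integer", height = "integer"),
  validity = function(object) {
    ok <- all(vapply(object@levels, is, logical(1), class2 = "ScaleLevel"))
    if (!ok) return("all levels must be ScaleLevel objects")
    idx <- vapply(object@levels, function(l) l@index, integer(1))
    if (!identical(idx, seq_along(idx))) return("levels must be k = 1..n in order")
    TRUE
  })

#' Per-scale feature density map
#'
#' Kernel density estimate of pooled blob-feature positions over the
#' normalized face frame \eqn{[0,1]^2}, evaluated on a fixed grid, plus the
#' model points selected from its local maxima (those within a fixed fraction
#' of the global maximum).
#'
#' @slot level integer scale index the features came from.
#' @slot grid numeric matrix \code{[x, y]}; non-negative, sums to
#'   1 / cellArea so that the map integrates to one over the unit square.
#' @slot nImages number of images whose features were pooled.
#' @slot bandwidth numeric length-2 KDE bandwidth (x, y) in frame units.
#' @slot modelPoints two-column matrix of normalized (x, y) model points.
#' @name FeatureDensityMap-class
#' @exportClass FeatureDensityMap
setClass("FeatureDensityMap",
  representation(level = "integer", grid = "matrix", nImages = "integer",
                 bandwidth = "numeric", modelPoints = "matrix"),
  validity = function(object) {
    msg <- character()
    if (any(object@grid < 0)) msg <- c(msg, "grid values must be non-negative")
    cell <- 1 / nrow(object@grid) / ncol(object@grid)
    if (abs(sum(object@grid) * cell - 1) > 1e-6)
      msg <- c(msg, "grid must integrate to 1 over the unit square")
    if (nrow(object@modelPoints) && ncol(object@modelPoints) != 2L)
      msg <- c(msg, "modelPoints must have two columns")
    if (length(msg)) msg else TRUE
  })

#' Binary patch classifier for one model scale
#'
#' A linear max-margin (SVM) separator over 144-component HOG patch
#' descriptors. Stored as an explicit weight vector + bias so classification
#' reduces to a dot product; output is hard 0/1.
#'
#' @slot level scale index the classifier belongs to.
#' @slot weights numeric length-144 weight vector.
#' @slot bias numeric scalar; decision value is `x . w + bias`, label 1 iff > 0.
#' @slot meta list of training metadata (nPos, nNeg, seed, cost).
#' @name PatchClassifier-class
#' @exportClass PatchClassifier
setClass("PatchClassifier",
  representation(level = "integer", weights = "numeric", bias = "numeric",
                 meta = "list"),
  validity = function(object) {
    if (length(object@bias) != 1L) return("bias must be scalar")
    TRUE
  })

#' Eye-tracking fixation records
#'
#' Fixations of observers on face images, in the normalized face frame.
#' Columns: \code{observer_id}, \code{image_id}, \code{fixation_index}
#' (ordinal position of the fixation in an observer's viewing sequence,
#' 1-based), \code{x}, \code{y} in \eqn{[0,1]^2}, and optionally
#' \code{duration_ms}.
#'
#' @slot records data.frame of fixation records.
#' @name FixationSet-class
#' @exportClass FixationSet
setClass("FixationSet",
  representation(records = "data.frame"),
  validity = function(object) {
    req <- c("observer_id", "image_id", "fixation_index", "x", "y")
    if (!all(req %in% names(object@records)))
      return(paste("records must have columns", paste(req, collapse = ", ")))
    r <- object@records
    if (nrow(r)) {
      if (any(r$fixation_index < 1)) return("fixation_index must be >= 1")
      if (any(r$x < 0 | r$x > 1 | r$y < 0 | r$y > 1))
        return("coordinates must lie in [0,1]^2")
    }
    TRUE
  })

#' Multi-scale face model
#'
#' An ordered coarse-to-fine list of scale levels, each carrying the model
#' points selected from its feature density map and a trained binary patch
#' classifier. `referenceFacePx` is the size (pixels) a hypothesized face
#' frame spans at the coarsest stage of the detection cascade.
#'
#' @slot scales integer vector of levels, strictly decreasing (coarse first).
#' @slot modelPoints named list (by level) of two-column normalized (x, y)
#'   matrices.
#' @slot classifiers named list (by level) of [PatchClassifier-class] objects.
#' @slot referenceFacePx integer, default 32.
#' @slot patchSize integer, default 25.
#' @slot provenance list of training metadata.
#' @name FaceModel-class
#' @exportClass FaceModel
setClass("FaceModel",
  representation(scales = "integer", modelPoints = "list",
                 classifiers = "list", referenceFacePx = "integer",
                 patchSize = "integer", provenance = "list"),
  validity = function(object) {
    msg <- character()
    s <- object@scales
    if (length(s) < 1L) msg <- c(msg, "at least one scale required")
    if (length(s) > 1L && any(diff(s) >= 0))
      msg <- c(msg, "scales must be strictly decreasing (coarse to fine)")
    key <- as.character(s)
    if (!all(key %in% names(object@modelPoints)))
      msg <- c(msg, "every scale needs model points")
    else if (any(vapply(object@modelPoints[key], nrow, integer(1)) < 1L))
      msg <- c(msg, "every scale needs at least one model point")
    if (!all(key %in% names(object@classifiers)))
      msg <- c(msg, "every scale needs a trained classifier")
    if (object@patchSize %% 2L != 1L) msg <- c(msg, "patchSize must be odd")
    if (length(msg)) msg else TRUE
  })

## ---- accessors ----

#' @describeIn ScaleLevel-class list of ScaleLevel objects.
#' @param x an object.
#' @param ... unused.
#' @export
setMethod("scaleLevels", "ScaleSpacePyramid", function(x, ...) x@levels)

#' @describeIn ScaleLevel-class sigma of one level.
#' @export
setMethod("scaleSigma", "ScaleLevel", function(x, ...) x@sigma)

#' @describeIn ScaleLevel-class sigma schedule of the pyramid.
#' @export
setMethod("scaleSigma", "ScaleSpacePyramid", function(x, ...)
  vapply(x@levels, function(l) l@sigma, numeric(1)))

#' @describeIn ScaleLevel-class grid downsample factor of one level.
#' @export
setMethod("gridDownsample", "ScaleLevel", function(x, ...) x@gridDownsample)

#' @describeIn ScaleLevel-class the smoothed image of a level.
#' @export
setMethod("smoothedImage", "ScaleLevel", function(x, ...) x@smoothed)

#' @describeIn FeatureDensityMap-class the density grid.
#' @param x an object.
#' @param ... unused.
#' @export
setMethod("densityGrid", "FeatureDensityMap", function(x, ...) x@grid)

#' @describeIn FeatureDensityMap-class selected model points.
#' @export
setMethod("modelPoints", "FeatureDensityMap", function(x, ...) x@modelPoints)

#' @describeIn FeatureDensityMap-class number of pooled images.
#' @export
setMethod("nImages", "FeatureDensityMap", function(x, ...) x@nImages)

#' @describeIn FaceModel-class coarse-to-fine scale levels.
#' @export
setMethod("modelScales", "FaceModel", function(x, ...) x@scales)

#' @describeIn FaceModel-class named list of per-level model points.
#' @export
setMethod("modelPoints", "FaceModel", function(x, ...) x@modelPoints)

#' @describeIn FaceModel-class named list of per-level classifiers.
#' @export
setMethod("classifiers", "FaceModel", function(x, ...) x@classifiers)

#' @describeIn FixationSet-class the records data.frame.
#' @param x an object.
#' @param ... unused.
#' @export
setMethod("fixationRecords", "FixationSet", function(x, ...) x@records)

## ---- show methods ----

setMethod("show", "ScaleSpacePyramid", function(object) {
  cat(sprintf("ScaleSpacePyramid: %d levels, source %dx%d px\n",
              length(object@levels), object@width, object@height))
  for (l in object@levels)
    cat(sprintf("  k=%2d sigma=%7.3f grid 1/%d (%dx%d)\n", l@index, l@sigma,
                l@gridDownsample, nrow(l@smoothed), ncol(l@smoothed)))
})

setMethod("show", "FeatureDensityMap", function(object) {
  cat(sprintf(
    "FeatureDensityMap: level %d, %dx%d grid, %d images, %d model point(s)\n",
    object@level, nrow(object@grid), ncol(object@grid), object@nImages,
    nrow(object@modelPoints)))
})

setMethod("show", "PatchClassifier", function(object) {
  cat(sprintf("PatchClassifier: level %d, %d weights, bias %.4f\n",
              object@level, length(object@weights), object@bias))
})

setMethod("show", "FixationSet", function(object) {
  r <- object@records
  cat(sprintf("FixationSet: %d fixations, %d observer(s), %d image(s), indices %s\n",
              nrow(r), length(unique(r$observer_id)),
              length(unique(r$image_id)),
              if (nrow(r)) paste(range(r$fixation_index), collapse = "..") else "-"))
})

setMethod("show", "FaceModel", function(object) {
  cat(sprintf("FaceModel: scales [%s] (coarse to fine), reference face %d px, patch %d px\n",
              paste(object@scales, collapse = ", "), object@referenceFacePx,
              object@patchSize))
  for (k in object@scales)
    cat(sprintf("  level %d: %d model point(s)\n", k,
                nrow(object@modelPoints[[as.character(k)]])))
})
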