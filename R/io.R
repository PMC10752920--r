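# Readers/writers for the plain-text dialects the pipeline exchanges:
# feature CSV, fixation CSV, FDDB annotation/detection lists, and JSON
# archives for density maps and face models.

#' Read an image as a luminance matrix
#'
#' Reads PNG/JPEG (any format EBImage handles); RGB is converted to
#' luminance as 0.299 R + 0.587 G + 0.114 B.
#'
#' @param path image file.
#' @return numeric matrix `[x, y]` in [0, 1].
#' @export
readImageGray <- function(path) toLuminance(EBImage::readImage(path))

#' Write a matrix as a grayscale image
#' @param image numeric matrix; values are clamped to [0, 1].
#' @param path output file (format from extension).
#' @export
writeImageGray <- function(image, path) {
  EBImage::writeImage(EBImage::Image(pmin(pmax(image, 0), 1)), path)
  invisible(path)
}

#' Write/read feature points as CSV
#'
#' Header: `image_id,x,y,level,sigma,response,polarity`.
#'
#' @param features feature data.frame (see [detectExtrema]).
#' @param path CSV file.
#' @param imageId id recorded in the `image_id` column (default "image").
#' @export
writeFeaturesCSV <- function(features, path, imageId = "image") {
  out <- data.frame(image_id = if ("image_id" %in% names(features))
    features$image_id else imageId,
    features[, c("x", "y", "level", "sigma", "response", "polarity")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCSV
#' @export
readFeaturesCSV <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write/read fixation records as CSV
#'
#' Header: `observer_id,image_id,fixation_index,x,y[,duration_ms]`. On
#' reading, raw-pixel coordinates can be normalized by the source frame
#' size via `width`/`height` (`normalized = FALSE`).
#'
#' @param fixations a [FixationSet-class].
#' @param path CSV file.
#' @export
writeFixationsCSV <- function(fixations, path) {
  utils::write.csv(fixationRecords(fixations), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeFixationsCSV
#' @param normalized logical; FALSE means x/y are raw pixels to be divided
#'   by `width`/`height`.
#' @param width,height source frame size when `normalized = FALSE`.
#' @export
readFixationsCSV <- function(path, normalized = TRUE, width = NULL,
                             height = NULL) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!normalized) {
    if (is.null(width) || is.null(height))
      stop("raw-pixel fixations need width/height for normalization")
    r$x <- r$x / width
    r$y <- r$y / height
  }
  new("FixationSet", records = r)
}

#' Serialize a density map (JSON) and export it as a heatmap
#' @param map a [FeatureDensityMap-class].
#' @param path output file.
#' @export
writeDensityMap <- function(map, path) {
  jsonlite::write_json(list(
    level = map@level, n_images = map@nImages,
    grid_resolution = dim(map@grid), bandwidth = map@bandwidth,
    model_points = map@modelPoints, grid = map@grid),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDensityMap
#' @export
readDensityMap <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mp <- matrix(j$model_points, ncol = 2)
  colnames(mp) <- c("x", "y")
  new("FeatureDensityMap", level = as.integer(j$level),
      grid = matrix(j$grid, j$grid_resolution[1], j$grid_resolution[2]),
      nImages = as.integer(j$n_images), bandwidth = j$bandwidth,
      modelPoints = mp)
}

#' @rdname writeDensityMap
#' @export
exportDensityMapPNG <- function(map, path) {
  g <- map@grid
  writeImageGray(g / max(g), path)
}

#' Serialize/deserialize a trained face model (JSON archive)
#'
#' The archive bundles the scale list, per-scale model points, classifier
#' weights/bias/metadata, `referenceFacePx`, `patchSize` and provenance.
#'
#' @param model a [FaceModel-class].
#' @param path output file.
#' @export
writeFaceModel <- function(model, path) {
  key <- as.character(model@scales)
  jsonlite::write_json(list(
    format = "gazeface-model", version = 1L,
    scales = model@scales,
    reference_face_px = model@referenceFacePx,
    patch_size = model@patchSize,
    model_points = lapply(model@modelPoints[key], unname),
    classifiers = lapply(model@classifiers[key], function(c)
      list(level = c@level, weights = c@weights, bias = c@bias,
           meta = c@meta)),
    # provenance may hold non-serializable objects (e.g. density maps);
    # archive only the atomic metadata
    provenance = Filter(function(x) is.atomic(x) || is.list(x) &&
                          all(vapply(x, is.atomic, logical(1))),
                        model@provenance)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFaceModel
#' @export
readFaceModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "gazeface-model"))
    stop("not a face model archive")
  key <- as.character(j$scales)
  mp <- lapply(j$model_points, function(m) {
    m <- matrix(unlist(m), ncol = 2)
    colnames(m) <- c("x", "y")
    m
  })
  names(mp) <- key
  clf <- lapply(seq_along(key), function(i) {
    c <- if (is.data.frame(j$classifiers)) as.list(j$classifiers[i, ])
         else j$classifiers[[i]]
    new("PatchClassifier", level = as.integer(c$level),
        weights = as.numeric(unlist(c$weights)), bias = as.numeric(c$bias),
        meta = as.list(c$meta))
  })
  names(clf) <- key
  new("FaceModel", scales = as.integer(j$scales), modelPoints = mp,
      classifiers = clf, referenceFacePx = as.integer(j$reference_face_px),
      patchSize = as.integer(j$patch_size),
      provenance = as.list(j$provenance))
}

#' FDDB-dialect annotation and detection files
#'
#' Annotations: per image, a name line, a count line, then one
#' `major_radius minor_radius angle center_x center_y 1` line per face.
#' Detections: name line, count line, then `left top width height score`
#' lines.
#'
#' @param annotations named list (by image name) of ellipse data.frames
#'   with columns `ra`, `rb`, `theta`, `cx`, `cy`.
#' @param path output file.
#' @export
writeFDDBAnnotations <- function(annotations, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(annotations)) {
    e <- annotations[[nm]]
    writeLines(nm, con)
    writeLines(as.character(nrow(e)), con)
    for (i in seq_len(nrow(e)))
      writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f  1", e$ra[i], e$rb[i],
                         e$theta[i], e$cx[i], e$cy[i]), con)
  }
  invisible(path)
}

#' @rdname writeFDDBAnnotations
#' @export
readFDDBAnnotations <- function(path) {
  ln <- readLines(path)
  out <- list(); i <- 1L
  while (i <= length(ln)) {
    nm <- ln[i]; n <- as.integer(ln[i + 1L]); i <- i + 2L
    e <- data.frame(ra = numeric(0), rb = numeric(0), theta = numeric(0),
                    cx = numeric(0), cy = numeric(0))
    if (n > 0) {
      v <- do.call(rbind, lapply(ln[i:(i + n - 1L)], function(s)
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
      e <- data.frame(ra = v[, 1], rb = v[, 2], theta = v[, 3],
                      cx = v[, 4], cy = v[, 5])
      i <- i + n
    }
    out[[nm]] <- e
  }
  out
}

#' @rdname writeFDDBAnnotations
#' @param detections named list (by image name) of detection data.frames
#'   with columns `x`, `y`, `w`, `h`, `score`.
#' @export
writeFDDBDetections <- function(detections, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(detections)) {
    d <- detections[[nm]]
    writeLines(nm, con)
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(sprintf("%.3f %.3f %.3f %.3f %d", d$x[i], d$y[i], d$w[i],
                         d$h[i], as.integer(d$score[i])), con)
  }
  invisible(path)
}

#' @rdname writeFDDBAnnotations
#' @export
readFDDBDetections <- function(path) {
  ln <- readLines(path)
  out <- list(); i <- 1L
  while (i <= length(ln)) {
    nm <- ln[i]; n <- as.integer(ln[i + 1L]); i <- i + 2L
    d <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                    h = numeric(0), score = numeric(0))
    if (n > 0) {
      v <- do.call(rbind, lapply(ln[i:(i + n - 1L)], function(s)
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
      d <- data.frame(x = v[, 1], y = v[, 2], w = v[, 3], h = v[, 4],
                      score = v[, 5])
      i <- i + n
    }
    out[[nm]] <- d
  }
  out
}
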