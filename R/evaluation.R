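.asRect <- function(r) {
  if (is.data.frame(r)) r <- unlist(r[1, c("x", "y", "w", "h")])
  r <- as.numeric(r)
  if (length(r) != 4L) stop("a rect is (x, y, w, h)")
  r
}

#' Intersection over union of two rectangles
#'
#' Rectangles are (x, y, w, h) with 0-based, half-open pixel convention.
#'
#' @param a,b rects (numeric length-4 or single-row data.frames).
#' @return IoU in [0, 1].
#' @examples
#' rectIoU(c(0, 0, 1, 1), c(0.5, 0, 1, 1))  # 1/3
#' @export
rectIoU <- function(a, b) {
  a <- .asRect(a); b <- .asRect(b)
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stop("degenerate rect: width and height must be positive")
  iw <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

.rectMatrix <- function(r) {
  if (is.null(r) || (is.data.frame(r) && !nrow(r)))
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x", "y", "w", "h"))))
  if (is.data.frame(r)) return(as.matrix(r[, c("x", "y", "w", "h")]))
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  colnames(r) <- c("x", "y", "w", "h")[seq_len(ncol(r))]
  r[, c("x", "y", "w", "h"), drop = FALSE]
}

#' Match detections to ground truth with greedy one-to-one IoU matching
#'
#' Candidate pairs are processed in descending IoU order; a detection
#' matching a still-unmatched truth with IoU >= `threshold` becomes a true
#' positive. Every unmatched detection is a false positive (so a second,
#' "double" detection of an already-matched face counts as FP) and every
#' unmatched truth a false negative. Precision is reported as NA when there
#' are no detections.
#'
#' @param detections,truths rect sets (data.frames with x, y, w, h or
#'   matrices; possibly empty).
#' @param threshold IoU threshold for a true positive (default 0.5; the
#'   comparison is closed, >=).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `iou_threshold` and `matches` (data.frame detection/truth/iou).
#' @export
matchDetections <- function(detections, truths, threshold = 0.5) {
  D <- .rectMatrix(detections); G <- .rectMatrix(truths)
  nd <- nrow(D); ng <- nrow(G)
  matches <- data.frame(detection = integer(0), truth = integer(0),
                        iou = numeric(0))
  if (nd && ng) {
    iou <- matrix(0, nd, ng)
    for (i in seq_len(nd)) for (j in seq_len(ng))
      iou[i, j] <- rectIoU(D[i, ], G[j, ])
    ord <- order(iou, decreasing = TRUE)
    usedD <- logical(nd); usedG <- logical(ng)
    for (o in ord) {
      if (iou[o] < threshold) break
      i <- (o - 1L) %% nd + 1L
      j <- (o - 1L) %/% nd + 1L
      if (usedD[i] || usedG[j]) next
      usedD[i] <- usedG[j] <- TRUE
      matches <- rbind(matches, data.frame(detection = i, truth = j,
                                           iou = iou[o]))
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fp = nd - tp, fn = ng - tp,
       precision = if (nd) tp / nd else NA_real_,
       recall = if (ng) tp / ng else NA_real_,
       iou_threshold = threshold, matches = matches)
}

#' Precision/recall as the IoU threshold varies
#'
#' Aggregates matched/unmatched counts over a collection of images at each
#' IoU threshold. Both precision and recall are non-increasing in the
#' threshold.
#'
#' @param detectionsPerImage,truthsPerImage lists of per-image rect sets
#'   (parallel, same length).
#' @param thresholds IoU grid (default `seq(0, 1, by = 0.05)`).
#' @return data.frame with columns `threshold`, `tp`, `fp`, `fn`,
#'   `precision` (NA when no detections), `recall`.
#' @export
prCurve <- function(detectionsPerImage, truthsPerImage,
                    thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(length(detectionsPerImage) == length(truthsPerImage),
            length(detectionsPerImage) >= 1L)
  rows <- lapply(thresholds, function(t) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(detectionsPerImage)) {
      m <- matchDetections(detectionsPerImage[[i]], truthsPerImage[[i]], t)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn) tp / (tp + fn) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Bounding rectangle of a rotated ellipse
#'
#' Axis-aligned bounding box of an ellipse with major radius `ra`, minor
#' radius `rb` and major-axis angle `theta` (radians; 0 = major axis along
#' y, the FDDB upright-face convention): half-width
#' \eqn{\sqrt{r_a^2 \sin^2\theta + r_b^2 \cos^2\theta}}, half-height
#' \eqn{\sqrt{r_a^2 \cos^2\theta + r_b^2 \sin^2\theta}}.
#'
#' @param ra,rb major/minor radii (> 0).
#' @param theta angle in radians.
#' @param cx,cy center.
#' @return named numeric rect (x, y, w, h).
#' @export
ellipseToRect <- function(ra, rb, theta, cx, cy) {
  if (ra <= 0 || rb <= 0) stop("ellipse radii must be positive")
  hw <- sqrt(ra^2 * sin(theta)^2 + rb^2 * cos(theta)^2)
  hh <- sqrt(ra^2 * cos(theta)^2 + rb^2 * sin(theta)^2)
  c(x = cx - hw, y = cy - hh, w = 2 * hw, h = 2 * hh)
}
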