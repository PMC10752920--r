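# Synthetic fixtures: procedural aligned face images with landmark/box
# ground truth, clutter negatives, annotated multi-face scenes, and
# simulated per-observer fixation sequences. All generators are pure
# functions of their spec + seed.

#' Specification of a synthetic aligned face image
#'
#' Defaults emulate an aligned frontal portrait: a 250 px canvas mostly
#' filled by a skin-tone oval with dark Gaussian-profile blobs at the two
#' eyes, the nose and the mouth, mild texture noise, and small per-image
#' landmark jitter. All geometry is in normalized canvas coordinates.
#'
#' @param canvas canvas side in pixels (default 250).
#' @param ovalCenter,ovalAxes face oval center and semi-axes (normalized).
#' @param landmarks named list of normalized (x, y) landmark positions.
#' @param blobSigma named list of per-landmark Gaussian radii (x, y).
#' @param blobContrast named list of per-landmark darkening amplitudes.
#' @param extras named list of additional rendered facial structure
#'   (eyebrows, eye sockets, hair mass, chin shadow), each a list with
#'   `pos`, `sigma`, `amp`; these give the face its coarse-scale blob
#'   structure but are not part of the ground-truth landmark set.
#' @param jitter landmark position jitter standard deviation (default 0.01).
#' @param noiseSd pixel texture noise standard deviation (default 0.02).
#' @param background uniform background intensity, or NULL (default) to
#'   surround the face with seeded clutter of random mean level, emulating
#'   the uncontrolled backgrounds of in-the-wild face crops.
#' @param skin face intensity in [0, 1].
#' @param seed integer seed.
#' @return a `SyntheticFaceSpec` list.
#' @export
faceSpec <- function(canvas = 250L,
                     ovalCenter = c(0.5, 0.5),
                     ovalAxes = c(0.36, 0.44),
                     landmarks = list(left_eye = c(0.36, 0.38),
                                      right_eye = c(0.64, 0.38),
                                      nose = c(0.5, 0.56),
                                      mouth = c(0.5, 0.72)),
                     blobSigma = list(left_eye = c(0.014, 0.011),
                                      right_eye = c(0.014, 0.011),
                                      nose = c(0.011, 0.009),
                                      mouth = c(0.045, 0.010)),
                     blobContrast = list(left_eye = 0.45, right_eye = 0.45,
                                         nose = 0.25, mouth = 0.40),
                     extras = list(
                       left_pupil = list(pos = c(0.36, 0.38),
                                         sigma = c(0.006, 0.006), amp = 0.25),
                       right_pupil = list(pos = c(0.64, 0.38),
                                          sigma = c(0.006, 0.006), amp = 0.25),
                       left_nostril = list(pos = c(0.478, 0.565),
                                           sigma = c(0.007, 0.006), amp = 0.20),
                       right_nostril = list(pos = c(0.522, 0.565),
                                            sigma = c(0.007, 0.006), amp = 0.20),
                       left_brow = list(pos = c(0.36, 0.31),
                                        sigma = c(0.035, 0.009), amp = 0.30),
                       right_brow = list(pos = c(0.64, 0.31),
                                         sigma = c(0.035, 0.009), amp = 0.30),
                       left_socket = list(pos = c(0.36, 0.38),
                                          sigma = c(0.055, 0.040), amp = 0.10),
                       right_socket = list(pos = c(0.64, 0.38),
                                           sigma = c(0.055, 0.040), amp = 0.10),
                       hair = list(pos = c(0.5, 0.14),
                                   sigma = c(0.22, 0.075), amp = 0.28),
                       chin_shadow = list(pos = c(0.5, 0.80),
                                          sigma = c(0.10, 0.035), amp = 0.08)),
                     jitter = 0.01, noiseSd = 0.02,
                     background = NULL, skin = 0.65, seed = 1L) {
  for (nm in names(landmarks)) {
    l <- landmarks[[nm]]
    if (sum(((l - ovalCenter) / ovalAxes)^2) >= 1)
      stop(sprintf("landmark '%s' lies outside the face oval", nm))
  }
  structure(list(canvas = as.integer(canvas), ovalCenter = ovalCenter,
                 ovalAxes = ovalAxes, landmarks = landmarks,
                 blobSigma = blobSigma, blobContrast = blobContrast,
                 extras = extras,
                 jitter = jitter, noiseSd = noiseSd, background = background,
                 skin = skin, seed = as.integer(seed)),
            class = "SyntheticFaceSpec")
}

#' Render a synthetic face image
#'
#' Draws the face oval with its dark landmark blobs and texture noise and
#' returns the image together with ground truth: the jittered landmark
#' positions actually rendered and the face bounding box (the oval's
#' axis-aligned box, pixels). Bit-reproducible for a given spec.
#'
#' @param spec a [faceSpec] (its `seed` drives jitter and noise).
#' @return list with `image` (canvas x canvas matrix in [0, 1]),
#'   `landmarks` (named two-column matrix, normalized), `bbox`
#'   (x, y, w, h in pixels, 0-based half-open) and `spec`.
#' @export
generateFaceImage <- function(spec) {
  stopifnot(inherits(spec, "SyntheticFaceSpec"))
  set.seed(spec$seed)
  C <- spec$canvas
  # aligned face collections have uncontrolled, cluttered backgrounds:
  # unless the spec pins a uniform level, surround the oval with clutter
  bg <- if (is.null(spec$background))
    generateNegativeImage(size = C, nShapes = 15L, nEdges = 3L,
                          contrast = 0.18,
                          baseIntensity = stats::runif(1, 0.5, 0.9),
                          seed = spec$seed + 90021L)
  else spec$background
  set.seed(spec$seed + 1L)
  xs <- (seq_len(C) - 0.5) / C
  X <- matrix(xs, C, C)
  Y <- matrix(xs, C, C, byrow = TRUE)
  oc <- spec$ovalCenter; ax <- spec$ovalAxes
  # soft-edged oval: ~2 px transition
  d <- sqrt(((X - oc[1]) / ax[1])^2 + ((Y - oc[2]) / ax[2])^2)
  edge <- 2 / (C * min(ax))
  inside <- stats::plogis((1 - d) / edge)
  img <- bg + (spec$skin - bg) * inside
  lm <- matrix(NA_real_, length(spec$landmarks), 2,
               dimnames = list(names(spec$landmarks), c("x", "y")))
  for (nm in names(spec$landmarks)) {
    p <- spec$landmarks[[nm]] + stats::rnorm(2, 0, spec$jitter)
    s <- spec$blobSigma[[nm]]
    a <- spec$blobContrast[[nm]] * exp(stats::rnorm(1, 0, 0.1))
    img <- img - a * exp(-((X - p[1])^2 / (2 * s[1]^2) +
                           (Y - p[2])^2 / (2 * s[2]^2)))
    lm[nm, ] <- p
  }
  for (ex in spec$extras) {
    p <- ex$pos + stats::rnorm(2, 0, spec$jitter)
    a <- ex$amp * exp(stats::rnorm(1, 0, 0.1))
    img <- img - a * exp(-((X - p[1])^2 / (2 * ex$sigma[1]^2) +
                           (Y - p[2])^2 / (2 * ex$sigma[2]^2)))
  }
  if (spec$noiseSd > 0)
    img <- img + matrix(stats::rnorm(C * C, 0, spec$noiseSd), C, C)
  img <- pmin(pmax(img, 0), 1)
  bbox <- c(x = (oc[1] - ax[1]) * C, y = (oc[2] - ax[2]) * C,
            w = 2 * ax[1] * C, h = 2 * ax[2] * C)
  list(image = img, landmarks = lm, bbox = bbox, spec = spec)
}

#' Render a synthetic clutter (non-face) image
#'
#' Random soft ellipses of mixed contrast, a few straight shading edges and
#' pixel noise; no face-like landmark triad is constructed. Deterministic
#' per seed.
#'
#' @param size canvas side in pixels (default 250).
#' @param nShapes number of random blobs (default 25).
#' @param nEdges number of straight shading edges (default 4).
#' @param noiseSd pixel noise standard deviation (default 0.02).
#' @param baseIntensity mean background intensity (default 0.7).
#' @param contrast amplitude scale of the random shapes (default 0.25).
#' @param seed integer seed.
#' @return numeric `size` x `size` matrix in [0, 1].
#' @export
generateNegativeImage <- function(size = 250L, nShapes = 25L, nEdges = 4L,
                                  noiseSd = 0.02, baseIntensity = 0.7,
                                  contrast = 0.25, seed = 1L) {
  set.seed(as.integer(seed))
  C <- as.integer(size)
  xs <- (seq_len(C) - 0.5) / C
  X <- matrix(xs, C, C)
  Y <- matrix(xs, C, C, byrow = TRUE)
  img <- matrix(baseIntensity, C, C)
  for (i in seq_len(nShapes)) {
    p <- stats::runif(2)
    s <- stats::runif(2, 0.01, 0.12)
    a <- contrast * stats::runif(1, 0.2, 1) * sample(c(-1, 1), 1)
    img <- img + a * exp(-((X - p[1])^2 / (2 * s[1]^2) +
                           (Y - p[2])^2 / (2 * s[2]^2)))
  }
  for (i in seq_len(nEdges)) {
    th <- stats::runif(1, 0, pi)
    off <- stats::runif(1, 0.2, 0.8)
    a <- contrast * stats::runif(1, 0.2, 0.8) * sample(c(-1, 1), 1)
    img <- img + a * stats::plogis((cos(th) * X + sin(th) * Y - off) / 0.01)
  }
  if (noiseSd > 0) img <- img + matrix(stats::rnorm(C * C, 0, noiseSd), C, C)
  pmin(pmax(img, 0), 1)
}

#' Composite faces onto clutter and emit annotations
#'
#' Renders each requested face at full resolution, resizes its canvas to
#' the requested size, pastes it onto a clutter background at a random (or
#' given) non-overlapping position, and returns FDDB-style elliptical
#' ground truth (angle 0 = major axis vertical) plus the equivalent
#' axis-aligned rectangles.
#'
#' @param faceSizes integer vector of face-frame sizes in pixels (length =
#'   number of faces; may be empty for a face-free scene).
#' @param canvas scene side in pixels (default 256).
#' @param positions optional two-column matrix of top-left corners
#'   (0-based pixels); random non-overlapping placement if NULL.
#' @param seed integer seed (drives clutter, face rendering and placement).
#' @return list with `image`, `ellipses` (data.frame `ra`, `rb`, `theta`,
#'   `cx`, `cy`), `boxes` (data.frame `x`, `y`, `w`, `h`: oval bounding
#'   boxes) and `frames` (pasted face-frame boxes).
#' @export
generateScene <- function(faceSizes = integer(0), canvas = 256L,
                          positions = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  C <- as.integer(canvas)
  img <- generateNegativeImage(size = C, nShapes = 18L, nEdges = 3L,
                               contrast = 0.18, seed = as.integer(seed) + 101L)
  n <- length(faceSizes)
  ell <- data.frame(ra = numeric(0), rb = numeric(0), theta = numeric(0),
                    cx = numeric(0), cy = numeric(0))
  frames <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                       h = numeric(0))
  if (n) {
    if (is.null(positions)) {
      positions <- matrix(NA_real_, n, 2)
      placed <- matrix(numeric(0), 0, 3)  # x, y, size
      for (i in seq_len(n)) {
        s <- faceSizes[i]
        if (s > C) stop("face size exceeds scene canvas")
        for (try in 1:200) {
          p <- floor(stats::runif(2, 0, C - s + 1))
          ok <- !nrow(placed) || all(
            p[1] + s <= placed[, 1] | placed[, 1] + placed[, 3] <= p[1] |
            p[2] + s <= placed[, 2] | placed[, 2] + placed[, 3] <= p[2])
          if (ok) break
        }
        if (!ok) stop("could not place faces without overlap")
        positions[i, ] <- p
        placed <- rbind(placed, c(p, s))
      }
    }
    for (i in seq_len(n)) {
      s <- as.integer(faceSizes[i])
      sp <- faceSpec(seed = as.integer(seed) + 1000L + i)
      face <- generateFaceImage(sp)
      small <- resizeImage(face$image, s, s)
      px <- as.integer(positions[i, 1]); py <- as.integer(positions[i, 2])
      img[px + seq_len(s), py + seq_len(s)] <- small
      oc <- sp$ovalCenter; axl <- sp$ovalAxes
      ell <- rbind(ell, data.frame(
        ra = axl[2] * s, rb = axl[1] * s, theta = 0,
        cx = px + oc[1] * s - 0.5, cy = py + oc[2] * s - 0.5))
      frames <- rbind(frames, data.frame(x = px, y = py, w = s, h = s))
    }
  }
  boxes <- if (nrow(ell)) do.call(rbind, lapply(seq_len(nrow(ell)), function(i)
    as.data.frame(as.list(ellipseToRect(ell$ra[i], ell$rb[i], ell$theta[i],
                                        ell$cx[i], ell$cy[i])))))
    else data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                    h = numeric(0))
  list(image = img, ellipses = ell, boxes = boxes, frames = frames)
}

#' Observer models for fixation simulation
#'
#' Each observer gets a small idiosyncratic gaze bias and a personal noise
#' multiplier, emulating the observation that every viewer has their own
#' face-scanning strategy while all strategies cluster around the same
#' facial features.
#'
#' @param nObservers number of observers (default 20).
#' @param biasSd standard deviation of the per-observer bias (default 0.01).
#' @param seed integer seed.
#' @return list of per-observer lists (`bias`, `noiseMult`).
#' @export
observerModels <- function(nObservers = 20L, biasSd = 0.01, seed = 1L) {
  set.seed(as.integer(seed))
  lapply(seq_len(nObservers), function(i)
    list(bias = stats::rnorm(2, 0, biasSd),
         noiseMult = exp(stats::rnorm(1, 0, 0.15))))
}

# index-dependent attraction weights over (center, landmarks): early
# fixations land near the face center, later ones on the landmarks
.fixationWeights <- function(nFix, nLandmarks) {
  W <- matrix(0, nFix, nLandmarks + 1L)
  for (i in seq_len(nFix)) {
    wc <- max(0, 1 - (i - 1) / 4)
    W[i, 1] <- wc
    W[i, -1] <- (1 - wc) / nLandmarks
  }
  W
}

#' Simulate observer fixation sequences
#'
#' Draws, per observer and image, a sequence of fixations from an
#' index-dependent mixture over the face center and the landmarks: early
#' fixation indices are attracted to the center with broad scatter, later
#' indices to individual landmarks with tight scatter (a coarse-to-fine
#' schedule). Fixation noise shrinks linearly from `noiseCoarse` to
#' `noiseFine` over the sequence; observer bias and noise multipliers come
#' from [observerModels].
#'
#' @param landmarks named two-column matrix of normalized landmark
#'   positions (e.g. from [generateFaceImage]).
#' @param observers list from [observerModels].
#' @param nImages number of viewed images (default 120).
#' @param nFixations fixations per observer per image (default 12).
#' @param noiseCoarse,noiseFine fixation scatter at the first and last
#'   index (defaults 0.08 and 0.02).
#' @param seed integer seed.
#' @return a [FixationSet-class].
#' @export
generateFixations <- function(landmarks, observers = observerModels(),
                              nImages = 120L, nFixations = 12L,
                              noiseCoarse = 0.08, noiseFine = 0.02,
                              seed = 1L) {
  landmarks <- as.matrix(landmarks)
  set.seed(as.integer(seed))
  ctr <- colMeans(landmarks)
  comp <- rbind(center = ctr, landmarks)
  W <- .fixationWeights(nFixations, nrow(landmarks))
  sdIdx <- seq(noiseCoarse, noiseFine, length.out = nFixations)
  no <- length(observers)
  total <- no * nImages * nFixations
  obs <- rep(seq_len(no), each = nImages * nFixations)
  imgid <- rep(rep(seq_len(nImages), each = nFixations), times = no)
  fi <- rep(seq_len(nFixations), times = no * nImages)
  pick <- integer(total); xy <- matrix(0, total, 2)
  for (r in seq_len(total)) {
    k <- sample.int(nrow(comp), 1, prob = W[fi[r], ])
    o <- observers[[obs[r]]]
    p <- comp[k, ] + o$bias +
      stats::rnorm(2, 0, sdIdx[fi[r]] * o$noiseMult)
    xy[r, ] <- pmin(pmax(p, 0), 1)
  }
  new("FixationSet", records = data.frame(
    observer_id = obs, image_id = imgid, fixation_index = fi,
    x = xy[, 1], y = xy[, 2]))
}
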