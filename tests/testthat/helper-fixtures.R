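# Shared fixtures, built lazily and memoised for the whole test run.
# Heavy objects (the 300-face training collection and the trained models)
# are constructed once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# study-condition training collection: 300 aligned faces, 100 negatives
fxFaceImages <- function() fixture("faceImages", function()
  lapply(1:300, function(s) generateFaceImage(faceSpec(seed = s))$image))

fxNegImages <- function() fixture("negImages", function()
  lapply(1:100, function(s) generateNegativeImage(seed = 1000 + s)))

# linked scale-space features of every training face
fxFaceFeatures <- function() fixture("faceFeatures", function()
  lapply(fxFaceImages(), extractFeatures))

# fixation-guided two-scale model and the three-scale variant
fxModel74 <- function() fixture("model74", function()
  buildFaceModel(fxFaceImages(), fxNegImages(), levels = c(7L, 4L),
                 seed = 42L))

fxModel741 <- function() fixture("model741", function()
  buildFaceModel(fxFaceImages(), fxNegImages(), levels = c(7L, 4L, 1L),
                 seed = 42L))

# centered Gaussian test blob: dark spot of the given width on a canvas
# whose exact center falls on the coarse pyramid grids
renderBlob <- function(canvas, sd, amp = 0.5, dark = TRUE) {
  ctr <- canvas / 2 - 0.5
  xs <- (seq_len(canvas) - 1) - ctr
  X <- matrix(xs, canvas, canvas)
  Y <- t(X)
  base <- if (dark) 0.8 else 0.3
  base + (if (dark) -1 else 1) * amp * exp(-(X^2 + Y^2) / (2 * sd^2))
}

# brute-force 8-neighborhood extremum scan mirroring the documented
# semantics (strict extrema, Hessian definiteness, 1-px border, threshold)
bruteForceExtrema <- function(level, minResponse = 0.02) {
  L <- laplacianResponse(level)
  S <- smoothedImage(level)
  g <- gridDownsample(level)
  thr <- max(1e-12, 1e-9 * diff(range(S)), minResponse)
  nx <- nrow(L); ny <- ncol(L)
  out <- NULL
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    nb <- c(L[i - 1, j - 1], L[i, j - 1], L[i + 1, j - 1],
            L[i - 1, j],                  L[i + 1, j],
            L[i - 1, j + 1], L[i, j + 1], L[i + 1, j + 1])
    v <- L[i, j]
    if (abs(v) <= thr) next
    if (!(all(v > nb) || all(v < nb))) next
    d2x <- S[i - 1, j] - 2 * S[i, j] + S[i + 1, j]
    d2y <- S[i, j - 1] - 2 * S[i, j] + S[i, j + 1]
    dxy <- (S[i + 1, j + 1] - S[i + 1, j - 1] - S[i - 1, j + 1] +
            S[i - 1, j - 1]) / 4
    if (d2x * d2y - dxy^2 <= 0) next
    out <- rbind(out, c((i - 1) * g + (g - 1) / 2, (j - 1) * g + (g - 1) / 2))
  }
  out
}
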