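# Low-level image helpers. Images are numeric matrices [x, y], 0-based pixel
# centers; boundaries are handled by symmetric reflection throughout.

# symmetric (edge-inclusive) reflection of out-of-range indices, folding
# repeatedly so it stays valid even when the overhang exceeds the size
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    bad <- i < 1L
    if (any(bad)) i[bad] <- 1L - i[bad]
    bad <- i > n
    if (!any(bad) && all(i >= 1L)) break
    i[bad] <- 2L * n + 1L - i[bad]
  }
  i
}

# shift a matrix along dim d by s with symmetric reflection padding
.shiftReflect <- function(m, dx = 0L, dy = 0L) {
  m[.reflectIndex(seq_len(nrow(m)) - dx, nrow(m)),
    .reflectIndex(seq_len(ncol(m)) - dy, ncol(m)), drop = FALSE]
}

# separable Gaussian convolution with symmetric reflection at the borders
gaussianSmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(n) .reflectIndex(seq(1L - r, n + r), n)
  nx <- nrow(img); ny <- ncol(img)
  p <- img[pad(nx), , drop = FALSE]
  out <- matrix(0, nx, ny)
  for (t in seq_along(k))
    out <- out + k[t] * p[t:(t + nx - 1L), , drop = FALSE]
  p <- out[, pad(ny), drop = FALSE]
  out <- matrix(0, nx, ny)
  for (t in seq_along(k))
    out <- out + k[t] * p[, t:(t + ny - 1L), drop = FALSE]
  out
}

# factor-2 downsampling by area averaging (odd trailing row/col dropped)
downsample2 <- function(m) {
  nx <- 2L * (nrow(m) %/% 2L); ny <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nx), seq_len(ny), drop = FALSE]
  o <- seq(1L, nx, 2L); e <- seq(2L, nx, 2L)
  oc <- seq(1L, ny, 2L); ec <- seq(2L, ny, 2L)
  0.25 * (m[o, oc, drop = FALSE] + m[e, oc, drop = FALSE] +
          m[o, ec, drop = FALSE] + m[e, ec, drop = FALSE])
}

# resize with Gaussian pre-filter when shrinking (anti-aliasing)
resizeImage <- function(img, width, height = width) {
  f <- min(width / nrow(img), height / ncol(img))
  if (f < 1) {
    s <- 0.5 * sqrt(max(1 / f^2 - 1, 0))
    if (s > 0.1) img <- gaussianSmooth(img, s)
  }
  out <- EBImage::resize(EBImage::Image(img), w = width, h = height)
  matrix(EBImage::imageData(out), width, height)
}

# RGB array [x, y, 3] (or EBImage Image) to luminance matrix
toLuminance <- function(img) {
  if (is(img, "Image")) img <- EBImage::imageData(img)
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    nc <- dim(img)[3L]
    if (nc == 1L) return(img[, , 1L])
    out <- w[1] * img[, , 1L] + w[2] * img[, , 2L] + w[3] * img[, , 3L]
    return(out)
  }
  stop("unsupported image layout: expected matrix or [x, y, channel] array")
}

# symmetric reflection padding by p pixels on every side
padReflect <- function(m, p) {
  m[.reflectIndex(seq(1L - p, nrow(m) + p), nrow(m)),
    .reflectIndex(seq(1L - p, ncol(m) + p), ncol(m)), drop = FALSE]
}

# central-difference derivatives (reflected borders), grid units
.gradX <- function(m) (.shiftReflect(m, dx = -1L) - .shiftReflect(m, dx = 1L)) / 2
.gradY <- function(m) (.shiftReflect(m, dy = -1L) - .shiftReflect(m, dy = 1L)) / 2
.d2X <- function(m) .shiftReflect(m, dx = -1L) - 2 * m + .shiftReflect(m, dx = 1L)
.d2Y <- function(m) .shiftReflect(m, dy = -1L) - 2 * m + .shiftReflect(m, dy = 1L)
# fourth-order central second differences: the O(h^2) truncation error of
# the 3-point stencil is not scale-uniform on the downsampled grids and
# would bias the across-scale comparison of normalized responses
.d2X4 <- function(m) {
  (-.shiftReflect(m, dx = -2L) + 16 * .shiftReflect(m, dx = -1L) - 30 * m +
   16 * .shiftReflect(m, dx = 1L) - .shiftReflect(m, dx = 2L)) / 12
}
.d2Y4 <- function(m) {
  (-.shiftReflect(m, dy = -2L) + 16 * .shiftReflect(m, dy = -1L) - 30 * m +
   16 * .shiftReflect(m, dy = 1L) - .shiftReflect(m, dy = 2L)) / 12
}
.dXY <- function(m) {
  (.shiftReflect(m, dx = -1L, dy = -1L) - .shiftReflect(m, dx = -1L, dy = 1L) -
   .shiftReflect(m, dx = 1L, dy = -1L) + .shiftReflect(m, dx = 1L, dy = 1L)) / 4
}
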