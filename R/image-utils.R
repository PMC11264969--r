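# Shared raster utilities: bicubic/bilinear sampling, rotation/translation
# about the image centre, Fourier helpers and sub-pixel peak refinement.
# Conventions (documented in the methods vignette): stored arrays are
# [row, col] with row 1 at the top; translations (dx, dy) are in pixels,
# positive right/down; rotation angles are counter-clockwise positive with
# the x axis pointing right and the y axis pointing up.

# Keys cubic-convolution kernel, a = -0.5 (the classic bicubic weight).
keysWeight <- function(t) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  i2 <- !i1 & t < 2
  w[i1] <- 1.5 * t[i1]^3 - 2.5 * t[i1]^2 + 1
  w[i2] <- -0.5 * t[i2]^3 + 2.5 * t[i2]^2 - 4 * t[i2] + 2
  w
}

#' Sample an image at fractional coordinates
#'
#' Interpolates \code{img} at (row, col) positions \code{rs}, \code{cs}
#' (1-based, fractional). Positions outside the support are filled with
#' \code{fill}.
#'
#' @param img numeric matrix.
#' @param rs,cs equal-length numeric vectors of row/column coordinates.
#' @param method \code{"bicubic"} (Keys kernel) or \code{"bilinear"}.
#' @param fill value for out-of-support samples (default: image mean).
#' @return numeric vector of sampled values.
#' @keywords internal
sampleImage <- function(img, rs, cs, method = c("bicubic", "bilinear"),
                        fill = mean(img)) {
  method <- match.arg(method)
  n1 <- nrow(img); n2 <- ncol(img)
  out <- rep(fill, length(rs))
  inside <- rs >= 1 & rs <= n1 & cs >= 1 & cs <= n2
  if (!any(inside)) return(out)
  r <- rs[inside]; ci <- cs[inside]
  if (method == "bilinear") {
    r0 <- floor(r); c0 <- floor(ci)
    fr <- r - r0; fc <- ci - c0
    r0 <- pmin(pmax(r0, 1), n1); c0 <- pmin(pmax(c0, 1), n2)
    r1 <- pmin(r0 + 1, n1); c1 <- pmin(c0 + 1, n2)
    v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
         (1 - fr) * fc       * img[cbind(r0, c1)] +
         fr       * (1 - fc) * img[cbind(r1, c0)] +
         fr       * fc       * img[cbind(r1, c1)]
  } else {
    r0 <- floor(r); c0 <- floor(ci)
    fr <- r - r0; fc <- ci - c0
    v <- numeric(length(r))
    wsum <- numeric(length(r))
    for (dr in -1:2) {
      wr <- keysWeight(dr - fr)
      rr <- pmin(pmax(r0 + dr, 1), n1)   # clamp: replicate edge rows
      for (dc in -1:2) {
        wc <- keysWeight(dc - fc)
        cc <- pmin(pmax(c0 + dc, 1), n2)
        w <- wr * wc
        v <- v + w * img[cbind(rr, cc)]
        wsum <- wsum + w
      }
    }
    v <- v / wsum
  }
  out[inside] <- v
  out
}

#' Rotate an image about its centre
#'
#' Output has the same size as the input; pixels whose source falls outside
#' the frame are filled with \code{fill}. Positive angles rotate the image
#' content counter-clockwise (x right, y up).
#'
#' @param img numeric matrix (square or not).
#' @param degrees rotation angle in degrees.
#' @param method interpolation method, see [sampleImage()].
#' @param fill fill value (default: image mean).
#' @return rotated matrix of the same size.
#' @export
rotateImage <- function(img, degrees, method = "bicubic", fill = mean(img)) {
  n1 <- nrow(img); n2 <- ncol(img)
  th <- degrees * pi / 180
  cy <- (n1 + 1) / 2; cx <- (n2 + 1) / 2
  g <- expand.grid(r = seq_len(n1), c = seq_len(n2))
  x <- g$c - cx
  y <- cy - g$r            # y up
  xs <- cos(th) * x + sin(th) * y
  ys <- -sin(th) * x + cos(th) * y
  v <- sampleImage(img, cy - ys, cx + xs, method = method, fill = fill)
  matrix(v, n1, n2)
}

#' Translate an image by a (possibly fractional) pixel shift
#'
#' Shifts content by \code{dx} to the right and \code{dy} downwards;
#' uncovered pixels are filled with \code{fill}.
#'
#' @inheritParams rotateImage
#' @param dx,dy shift in pixels (positive right/down).
#' @return shifted matrix of the same size.
#' @export
translateImage <- function(img, dx, dy, method = "bicubic",
                           fill = mean(img)) {
  n1 <- nrow(img); n2 <- ncol(img)
  g <- expand.grid(r = seq_len(n1), c = seq_len(n2))
  v <- sampleImage(img, g$r - dy, g$c - dx, method = method, fill = fill)
  matrix(v, n1, n2)
}

# Resample an arbitrary axis-aligned source window (possibly rotated and/or
# mirrored) onto a size x size output: the workhorse of the augmentation
# pipeline. The window is given by its centre (rc, cc), side `side` (source
# pixels), rotation `degrees` and an optional horizontal flip.
resampleWindow <- function(img, rc, cc, side, size, degrees = 0,
                           flip = FALSE, method = "bilinear",
                           fill = mean(img)) {
  scale <- side / size
  if (scale > 1.2) {
    # anti-alias before minification: point-sampling a noisy image keeps
    # the full noise power, a matched low-pass averages it away
    img <- blurImage(img, 0.5 * scale)
  }
  th <- degrees * pi / 180
  u <- (seq_len(size) - (size + 1) / 2) * side / size
  g <- expand.grid(y = u, x = u)
  x <- if (flip) -g$x else g$x
  y <- -g$y               # grid row increases downwards; flip to y-up
  xs <- cos(th) * x + sin(th) * y
  ys <- -sin(th) * x + cos(th) * y
  v <- sampleImage(img, rc - ys, cc + xs, method = method, fill = fill)
  matrix(v, size, size)
}

# fftshift / inverse fftshift for matrices (centre the zero frequency).
fftShift2 <- function(m) {
  d <- dim(m)
  s1 <- floor(d[1L] / 2); s2 <- floor(d[2L] / 2)
  m[c((s1 + 1):d[1L], 1:s1), c((s2 + 1):d[2L], 1:s2)]
}

iFftShift2 <- function(m) {
  d <- dim(m)
  s1 <- ceiling(d[1L] / 2); s2 <- ceiling(d[2L] / 2)
  m[c((s1 + 1):d[1L], 1:s1), c((s2 + 1):d[2L], 1:s2)]
}

# Circular (periodic) Gaussian blur via the Fourier transform.
blurImage <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n1 <- nrow(img); n2 <- ncol(img)
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  H <- exp(-2 * pi^2 * sigma^2 * outer(f1^2, f2^2, `+`))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (n1 * n2)
}

# Extract a (2*halo+1)^2 window around (pr, pc) from a matrix that is
# periodic in both axes (cross-correlation surfaces are).
wrapWindow <- function(m, pr, pc, halo) {
  d <- dim(m)
  ri <- ((pr - halo - 1):(pr + halo - 1)) %% d[1L] + 1L
  ci <- ((pc - halo - 1):(pc + halo - 1)) %% d[2L] + 1L
  m[ri, ci]
}

#' Refine a correlation peak to sub-cell precision
#'
#' Bicubic interpolation on an upsampled grid around the integer maximum of a
#' periodic correlation surface: a 5x5 neighbourhood is scanned at 10x
#' upsampling (0.1-cell granularity) by default.
#'
#' @param m correlation matrix (periodic in both axes).
#' @param window odd window size scanned around the integer peak.
#' @param upsample upsampling factor within the window.
#' @return list with \code{row}, \code{col}: fractional peak position, and
#'   \code{value}: interpolated peak height.
#' @keywords internal
refinePeak <- function(m, window = 5L, upsample = 10L) {
  p <- which(m == max(m), arr.ind = TRUE)
  # ties: lowest column (angular) index, then lowest row
  p <- p[order(p[, 2L], p[, 1L]), , drop = FALSE][1L, ]
  halo <- (window - 1L) %/% 2L
  W <- wrapWindow(m, p[1L], p[2L], halo + 2L)  # +2 rows/cols of support
  off <- seq(-halo, halo, by = 1 / upsample)
  ctr <- halo + 3L                             # centre index inside W
  g <- expand.grid(r = off, c = off)
  v <- sampleImage(W, ctr + g$r, ctr + g$c, method = "bicubic")
  i <- which.max(v)
  list(row = p[1L] + g$r[i], col = p[2L] + g$c[i], value = v[i])
}

# Deterministic scoped RNG: run fn under a seed without disturbing the
# caller's RNG stream.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

# Derive a child seed from (seed, salt) pairs, kept below 2^31.
childSeed <- function(seed, ...) {
  x <- as.numeric(seed)
  for (s in list(...)) {
    x <- (x * 69069 + as.numeric(s) * 2654435761 + 1) %% 2147483647
  }
  as.integer(x)
}
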