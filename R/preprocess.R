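# Preprocessing: per-image normalisation, histogram equalisation and
# circular masking. All three operate image-by-image, so processing a stack
# equals processing each image independently.

#' Normalise an image to zero mean and unit variance
#'
#' A constant image maps to all zeros (the degenerate-input convention used
#' throughout the package).
#'
#' @param img numeric matrix.
#' @return normalised matrix.
#' @export
normalizeImage <- function(img) {
  s <- stats::sd(as.vector(img))
  if (!is.finite(s) || s == 0) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  (img - mean(img)) / s
}

#' Histogram equalisation on a 65536-bin quantisation
#'
#' Classic CDF remapping: intensities are quantised to 65536 levels and each
#' pixel is replaced by the empirical CDF value of its level, flattening the
#' histogram towards uniform. The map is monotone (ties may merge); output
#' lies in [0, 1]; a constant image maps to 0.
#'
#' @param img numeric matrix.
#' @return equalised matrix with values in [0, 1].
#' @export
histEqualize <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) stop("image must be finite")
  if (rng[2L] == rng[1L]) return(matrix(0, nrow(img), ncol(img)))
  q <- as.integer(floor((img - rng[1L]) / (rng[2L] - rng[1L]) * 65535))
  counts <- tabulate(q + 1L, nbins = 65536L)
  cdf <- cumsum(counts) / length(img)
  matrix(cdf[q + 1L], nrow(img), ncol(img))
}

#' Apply a smooth circular mask
#'
#' Pixels outside a centred circle of radius \code{radiusFrac * n/2} are
#' replaced by the inside-mask mean; the transition is a 3-pixel cosine
#' edge. Masking suppresses edge-driven spectral leakage before rotational
#' alignment and removes background clutter before the network stages while
#' keeping delocalised signal near the particle.
#'
#' @param img square numeric matrix.
#' @param radiusFrac mask radius as a fraction of n/2, in (0, 1].
#' @param edge taper width in pixels.
#' @return masked matrix.
#' @export
applyCircularMask <- function(img, radiusFrac = 0.9, edge = 3) {
  if (radiusFrac <= 0 || radiusFrac > 1) stop("radiusFrac must be in (0, 1]")
  n1 <- nrow(img); n2 <- ncol(img)
  ctr1 <- (n1 + 1) / 2; ctr2 <- (n2 + 1) / 2
  r <- radiusFrac * min(n1, n2) / 2
  d <- sqrt(outer((seq_len(n1) - ctr1)^2, (seq_len(n2) - ctr2)^2, `+`))
  w <- matrix(0, n1, n2)
  w[d <= r - edge] <- 1
  tr <- d > r - edge & d < r
  w[tr] <- 0.5 * (1 + cos(pi * (d[tr] - (r - edge)) / edge))
  m <- mean(img[d < r])
  if (!is.finite(m)) m <- mean(img)
  out <- img
  edge_or_out <- w < 1
  out[edge_or_out] <- m + w[edge_or_out] * (img[edge_or_out] - m)
  out
}

#' Preprocess a particle stack
#'
#' Applies, in order: per-image normalisation, optional histogram
#' equalisation, and circular masking. Equalisation is off by default for
#' simulated data (its contrast is already controlled) and intended for
#' low-contrast experimental images.
#'
#' @param stack a [ParticleStack-class].
#' @param normalize,equalize,mask stage switches.
#' @param radiusFrac mask radius fraction, see [applyCircularMask()].
#' @return a [ParticleStack-class] of processed images.
#' @export
preprocessStack <- function(stack, normalize = TRUE, equalize = FALSE,
                            mask = TRUE, radiusFrac = 0.9) {
  imgs <- stack@images
  for (k in seq_len(nImages(stack))) {
    im <- imgs[, , k]
    if (normalize) im <- normalizeImage(im)
    if (equalize) im <- histEqualize(im)
    if (mask) im <- applyCircularMask(im, radiusFrac)
    imgs[, , k] <- im
  }
  ParticleStack(imgs, pixelSize = pixelSize(stack), ids = particleIds(stack))
}
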