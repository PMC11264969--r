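# Frequency-domain in-plane alignment.
#
# Rotation: the magnitude of the centred 2D Fourier transform is resampled
# on a polar grid ((n/2) radii x 360 one-degree angles); rotating the image
# circularly shifts this map along its angular axis while translation
# leaves it unchanged, so the rotation angle is read from the angular
# position of the peak of the 2D cross-correlation of the two polar maps
# (computed by FFT, centred, and refined by bicubic interpolation at 10x
# upsampling). Because magnitude spectra of real images are centrosymmetric
# (Friedel symmetry), the angle is recovered modulo 180 degrees; the two
# candidates are scored by real-space correlation and the better one kept.
# Translation: standard Cartesian cross-correlation via the FFT with the
# same sub-cell peak refinement, wrap-around disambiguated to |d| < n/2.

#' Polar Fourier magnitude spectrum
#'
#' The centred magnitude spectrum bilinearly resampled at radii
#' \code{0:(n/2-1)} and angles \code{0:359} degrees.
#'
#' @param img square numeric matrix with even side n.
#' @return \code{(n/2) x 360} matrix; rows are radii, columns angles.
#' @export
polarSpectrum <- function(img) {
  n <- nrow(img)
  if (ncol(img) != n) stop("image must be square")
  if (n %% 2L != 0L) stop("image side must be even")
  Fm <- fftShift2(Mod(stats::fft(img)))
  ctr <- n / 2 + 1                      # DC after fftshift
  rad <- 0:(n / 2 - 1)
  ang <- (0:359) * pi / 180
  rs <- ctr - outer(rad, sin(ang))      # y up
  cs <- ctr + outer(rad, cos(ang))
  v <- sampleImage(Fm, as.vector(rs), as.vector(cs), method = "bilinear",
                   fill = 0)
  matrix(v, n / 2, 360L)
}

#' Cross-correlation of two polar spectra
#'
#' \code{P = |ifft2(fft2(Fi) * conj(fft2(Fj)))|}, circularly shifted by half
#' the matrix length on both axes so the zero-offset peak sits at the
#' centre, with the peak refined by bicubic interpolation on a 5x5 window
#' at 10x upsampling. The angular (column) offset of the peak is the
#' in-plane rotation estimate in degrees (1 cell = 1 degree).
#'
#' @param Fi,Fj polar spectra from [polarSpectrum()], equal shapes.
#' @param center circularly centre the surface (default); disable to keep
#'   the raw FFT layout with the zero-offset peak at cell (1, 1).
#' @return list: \code{P} the correlation surface, \code{peak} the
#'   fractional (row, col) of the refined maximum, \code{angleOffset} the
#'   angular offset in cells (degrees) in (-180, 180], and \code{value}.
#' @export
rotationCorrelation <- function(Fi, Fj, center = TRUE,
                                maxRadialShift = NULL) {
  if (!all(dim(Fi) == dim(Fj))) stop("spectra must have equal shapes")
  P <- Mod(stats::fft(stats::fft(Fi) * Conj(stats::fft(Fj)),
                      inverse = TRUE)) / length(Fi)
  if (center) P <- fftShift2(P)
  Psearch <- P
  if (center && !is.null(maxRadialShift)) {
    # a true rotation shifts only the angular axis; confining the peak
    # search to near-zero radial shifts rejects spurious off-axis maxima
    z <- floor(nrow(P) / 2) + 1L
    keep <- max(1L, z - maxRadialShift):min(nrow(P), z + maxRadialShift)
    Psearch[setdiff(seq_len(nrow(P)), keep), ] <- 0
  }
  d <- dim(P)
  zero <- if (center) c(floor(d[1L] / 2) + 1L, floor(d[2L] / 2) + 1L) else c(1L, 1L)
  if (center) {
    # magnitude maps are 180-degree periodic (Friedel symmetry), so the
    # +/-180 peaks tie exactly; prefer the candidate nearest zero offset
    mx <- max(Psearch)
    cand <- which(Psearch >= mx * (1 - 1e-9), arr.ind = TRUE)
    dist <- abs(((cand[, 2L] - zero[2L] + d[2L] / 2) %% d[2L]) - d[2L] / 2)
    keepRC <- cand[which.min(dist), ]
    mask <- matrix(0, d[1L], d[2L])
    halo <- 4L
    rI <- ((keepRC[1L] - halo - 1L):(keepRC[1L] + halo - 1L)) %% d[1L] + 1L
    cI <- ((keepRC[2L] - halo - 1L):(keepRC[2L] + halo - 1L)) %% d[2L] + 1L
    mask[rI, cI] <- 1
    Psearch <- Psearch * mask
  }
  pk <- refinePeak(Psearch)
  off <- unname(pk$col - zero[2L])
  off <- ((off + d[2L] / 2) %% d[2L]) - d[2L] / 2
  list(P = P, peak = c(row = pk$row, col = pk$col), angleOffset = off,
       value = pk$value)
}

#' Wrap an angle to (-pi, pi]
#'
#' The piecewise map: angles in \code{[0, pi]} are kept; angles in
#' \code{(pi, 2*pi)} map to \code{angle - 2*pi}. Arbitrary finite input is
#' first reduced modulo \code{2*pi}, which makes the map idempotent.
#'
#' @param omega angle in radians.
#' @return wrapped angle in \code{(-pi, pi]}.
#' @examples
#' wrapAngle(3 * pi / 2)  # -pi/2
#' wrapAngle(pi)          # pi
#' @export
wrapAngle <- function(omega) {
  if (any(!is.finite(omega))) stop("angle must be finite")
  w <- omega %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

# Rotation-invariant preprocessing used before spectral comparison.
alignPrep <- function(img, radiusFrac = 0.9) {
  applyCircularMask(normalizeImage(img), radiusFrac)
}

#' Estimate the in-plane rotation between two images
#'
#' Cross-correlates the polar magnitude spectra of the masked, normalised
#' images and reads the rotation from the angular peak position. The
#' 180-degree Friedel ambiguity is resolved by rotating the mover by both
#' candidate angles and keeping the one with the higher real-space
#' correlation against the reference.
#'
#' @param imgRef,imgMov square images of equal (even) size.
#' @param radiusFrac mask radius used in the preprocessing.
#' @return list: \code{omega} (radians in (-pi, pi]), \code{omegaDeg},
#'   \code{ambiguityResolved} (always TRUE on success), \code{score} (the
#'   winning real-space correlation).
#' @export
estimateRotation <- function(imgRef, imgMov, radiusFrac = 0.9,
                             polish = TRUE) {
  if (!all(dim(imgRef) == dim(imgMov))) stop("images must match in size")
  if (stats::sd(as.vector(imgRef)) == 0 || stats::sd(as.vector(imgMov)) == 0) {
    stop("undefined rotation for a flat image")
  }
  aRef <- alignPrep(imgRef, radiusFrac)
  aMov <- alignPrep(imgMov, radiusFrac)
  # sqrt-compressed polar maps with the lowest radii removed: the near-DC
  # cells carry no angular information but dominate the raw magnitudes
  Fi <- rotWeight(polarSpectrum(aMov))
  Fj <- rotWeight(polarSpectrum(aRef))
  rc <- rotationCorrelation(Fi, Fj, maxRadialShift = 2L)
  cand <- c(rc$angleOffset, rc$angleOffset + 180)
  # Friedel disambiguation and polish both score a candidate angle by
  # de-rotating the raw mover (its background is its own fill value, so no
  # edge step is introduced), compensating the translation estimated AT
  # that angle, and correlating with the reference. Estimating the
  # translation per candidate angle avoids the joint local optima that
  # trap a simple alternating scheme on smooth particles.
  # a mild low-pass (sigma 1 px) suppresses pixel noise before scoring:
  # the rotation signal lives at low/mid frequencies, the noise does not
  jRef <- blurImage(imgRef, 1)
  jMov <- blurImage(imgMov, 1)
  bg <- stats::median(jMov)
  jointScore <- function(a) {
    r1 <- rotateImage(jMov, -a, fill = bg)
    tr <- estimateTranslation(jRef, r1)
    stats::cor(as.vector(jRef),
               as.vector(translateImage(r1, -tr$dx, -tr$dy, fill = bg)))
  }
  # coarse sweep around both candidates: the spectral estimate can be a
  # few degrees off, and the ambiguity is settled on the same score
  grid <- as.vector(outer(seq(-8, 8, by = 2), cand, `+`))
  sc <- vapply(grid, jointScore, numeric(1L))
  best <- grid[which.max(sc)]
  if (polish) {
    for (sp in list(c(1.5, 0.25), c(0.25, 0.05), c(0.05, 0.01))) {
      grid <- best + seq(-sp[1L], sp[1L], by = sp[2L])
      sc <- vapply(grid, jointScore, numeric(1L))
      best <- grid[which.max(sc)]
    }
  }
  list(omega = wrapAngle(best * pi / 180),
       omegaDeg = ((best + 180) %% 360) - 180, ambiguityResolved = TRUE,
       score = jointScore(best))
}

# Radial weighting for rotation estimation: compress the dynamic range and
# drop radii < 3 (no angular content) and the outermost two rings.
rotWeight <- function(pm) {
  w <- rep(1, nrow(pm))
  w[seq_len(min(3L, nrow(pm)))] <- 0
  if (nrow(pm) > 2L) w[nrow(pm) - c(0L, 1L)] <- 0
  sqrt(pm) * w
}

#' Estimate the translation between two images
#'
#' Cartesian cross-correlation via the FFT (rotation is assumed already
#' compensated), with the integer peak refined by the same 5x5 / 10x
#' bicubic interpolation and wrap-around resolved to \code{|dx|, |dy| <
#' n/2}.
#'
#' @param imgRef,imgMov square images of equal size.
#' @return list: \code{dx}, \code{dy} in pixels (positive right/down:
#'   \code{translateImage(imgRef, dx, dy)} best matches \code{imgMov}),
#'   and \code{score} (peak height).
#' @export
estimateTranslation <- function(imgRef, imgMov) {
  if (!all(dim(imgRef) == dim(imgMov))) stop("images must match in size")
  if (stats::sd(as.vector(imgRef)) == 0 || stats::sd(as.vector(imgMov)) == 0) {
    stop("undefined shift for a flat image")
  }
  a <- normalizeImage(imgRef)
  b <- normalizeImage(imgMov)
  X <- stats::fft(b) * Conj(stats::fft(a))
  P <- Re(stats::fft(X, inverse = TRUE)) / length(a)
  P <- fftShift2(P)
  n <- nrow(a)
  zero <- floor(n / 2) + 1
  pk <- which(P == max(P), arr.ind = TRUE)[1L, ]
  dy <- pk[1L] - zero; dx <- pk[2L] - zero
  # sub-pixel refinement: evaluate the correlation on upsampled local
  # grids by explicit Fourier summation (two passes: 0.1 px then 0.01 px)
  f <- c(0:(n %/% 2 - 1L), -(n %/% 2):-1L)
  for (pass in list(c(1, 0.1), c(0.1, 0.01))) {
    sy <- dy + seq(-pass[1L], pass[1L], by = pass[2L])
    sx <- dx + seq(-pass[1L], pass[1L], by = pass[2L])
    # correlation convention: P(s) = ifft(X), i.e. C(s) = sum_k X_k
    # exp(+2*pi*i*<k, s>/n)
    Er <- exp(2i * pi * outer(sy, f) / n)
    Ec <- exp(2i * pi * outer(f, sx) / n)
    Cs <- Re(Er %*% X %*% Ec) / length(a)
    ij <- which(Cs == max(Cs), arr.ind = TRUE)[1L, ]
    dy <- sy[ij[1L]]; dx <- sx[ij[2L]]
  }
  list(dy = dy, dx = dx, score = max(P))
}

#' Apply alignment parameters to an image
#'
#' Rotates by \code{-omega} about the centre, then translates by
#' \code{(-dx, -dy)} — i.e. undoes the estimated transform so the image
#' lands on its reference. Bicubic resampling; uncovered pixels take the
#' image mean.
#'
#' @param img square numeric matrix.
#' @param params list with \code{omega} (radians) and \code{dx}, \code{dy}
#'   (pixels), as returned by the estimators.
#' @return the aligned image.
#' @export
transformImage <- function(img, params) {
  out <- img
  omegaDeg <- params$omega * 180 / pi
  if (omegaDeg != 0) out <- rotateImage(out, -omegaDeg)
  if (params$dx != 0 || params$dy != 0) {
    out <- translateImage(out, -params$dx, -params$dy)
  }
  out
}

#' Align every member of a class to a reference
#'
#' For each non-excluded image: estimate the rotation against the
#' reference, undo it, estimate the translation on the rotation-compensated
#' image, apply it, then re-estimate the residual translation once more
#' (one refinement pass). Excluded ids are dropped and reported.
#'
#' @param stack a [ParticleStack-class] holding one class's members.
#' @param refIdx index (or id) of the reference image.
#' @param exclude character ids to drop (e.g. manually rejected particles).
#' @param radiusFrac mask radius for the rotation estimate.
#' @return list: \code{aligned} (a [ParticleStack-class]), \code{params}
#'   (data.frame id, omegaDeg, dx, dy, score), \code{excluded}.
#' @export
alignClass <- function(stack, refIdx = 1L, exclude = character(0),
                       radiusFrac = 0.9) {
  ids <- particleIds(stack)
  if (is.character(refIdx)) refIdx <- match(refIdx, ids)
  if (is.na(refIdx) || refIdx < 1L || refIdx > nImages(stack)) {
    stop("invalid reference index")
  }
  bad <- setdiff(exclude, ids)
  if (length(bad)) stop("unknown ids in exclusion list: ",
                        paste(bad, collapse = ", "))
  keep <- setdiff(ids, exclude)
  if (!length(keep)) stop("empty class after exclusion")
  ref <- getImage(stack, refIdx)
  alignedImgs <- vector("list", length(keep))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    img <- getImage(stack, keep[j])
    rot <- estimateRotation(ref, img, radiusFrac)
    r1 <- rotateImage(img, -rot$omegaDeg)
    tr <- estimateTranslation(ref, r1)
    t1 <- translateImage(r1, -tr$dx, -tr$dy)
    tr2 <- estimateTranslation(ref, t1)          # refinement pass
    aligned <- translateImage(r1, -(tr$dx + tr2$dx), -(tr$dy + tr2$dy))
    alignedImgs[[j]] <- aligned
    rows[[j]] <- data.frame(id = keep[j], omegaDeg = rot$omegaDeg,
                            dx = tr$dx + tr2$dx, dy = tr$dy + tr2$dy,
                            score = rot$score, stringsAsFactors = FALSE)
  }
  list(aligned = ParticleStack(alignedImgs, pixelSize = pixelSize(stack),
                               ids = keep),
       params = do.call(rbind, rows),
       excluded = intersect(exclude, ids))
}
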