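# Synthetic particle dataset simulator.
#
# Procedurally generated phantom volumes stand in for deposited density
# maps: a phantom is a sum of anisotropic Gaussian blobs, constrained to be
# asymmetric under in-plane rotation so that rotational alignment is
# identifiable. Projections are orthographic (parallel-beam) line integrals
# on a (rot, tilt) grid; images within a class share the projection
# direction and differ by a random in-plane rotation; noise is injected to
# a target SNR, defined throughout as var(signal) / var(noise).

#' Generate a procedural phantom volume
#'
#' A sum of \code{kBlobs} anisotropic Gaussian blobs at seeded random
#' positions (within 0.26 n of the centre), orientations and widths
#' (0.04-0.08 n). The result
#' is checked for in-plane asymmetry of its top view (best self-correlation
#' under any non-zero rotation must stay below 0.95); failing draws are
#' regenerated with a perturbed seed, at most 10 times.
#'
#' @param seed integer seed; the same seed always yields the same volume.
#' @param n grid side (even, >= 32); the volume is \code{n^3}.
#' @param kBlobs number of blobs (>= 3).
#' @param pixelSize voxel size in Angstrom.
#' @return a list with \code{density} (n x n x n array, axes [y, x, z]),
#'   \code{pixelSize} and \code{seed}.
#' @export
makePhantom <- function(seed, n = 104L, kBlobs = 8L, pixelSize = 1.34) {
  if (n %% 2L != 0L || n < 32L) stop("n must be even and >= 32")
  if (kBlobs < 3L) stop("kBlobs must be >= 3")
  for (attempt in 0:9) {
    s <- childSeed(seed, attempt)
    vol <- withSeed(s, function() phantomDraw(n, kBlobs))
    p0 <- apply(vol, c(1L, 2L), sum)          # top view (tilt = 0)
    if (selfCorrMax(p0) < 0.95) {
      return(list(density = vol, pixelSize = pixelSize, seed = seed))
    }
  }
  stop("could not generate an asymmetric phantom in 10 attempts")
}

phantomDraw <- function(n, kBlobs) {
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  g <- expand.grid(y = ax, x = ax, z = ax)
  X <- cbind(g$y, g$x, g$z)
  vol <- numeric(n^3)
  for (b in seq_len(kBlobs)) {
    cen <- stats::runif(3, -0.26 * n, 0.26 * n)
    sig <- stats::runif(3, 0.04 * n, 0.08 * n)
    R <- randomRotation3()
    A <- R %*% diag(1 / sig^2) %*% t(R)
    amp <- stats::runif(1, 0.4, 1.6)
    Xc <- X - matrix(cen, n^3, 3L, byrow = TRUE)
    q <- rowSums((Xc %*% A) * Xc)
    keep <- q < 25        # beyond 5 sigma the blob is numerically zero
    vol[keep] <- vol[keep] + amp * exp(-q[keep] / 2)
  }
  array(vol, c(n, n, n))
}

randomRotation3 <- function() {
  M <- matrix(stats::rnorm(9), 3L, 3L)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Largest Pearson correlation between an image and a rotated copy of
# itself. Rotations below 20 degrees are excluded: any band-limited image
# correlates strongly with a slightly rotated copy, so small angles say
# nothing about rotational symmetry.
selfCorrMax <- function(img) {
  max(vapply(seq(20, 340, by = 10), function(th) {
    stats::cor(as.vector(img), as.vector(rotateImage(img, th, fill = 0)))
  }, numeric(1L)))
}

#' Build a (rot, tilt) projection angle grid
#'
#' Rotation angles are sampled on the half-open interval
#' \code{[rot0, rotF)} — the count is \code{floor((rotF - rot0) / rotStep)}
#' — while tilt angles span the closed interval \code{[tilt0, tiltF]} with
#' both endpoints included when the step divides the range.
#'
#' @param rot0,rotF,rotStep rotation (azimuth) range and step, degrees.
#' @param tilt0,tiltF,tiltStep tilt range and step, degrees.
#' @return data.frame with columns \code{rot}, \code{tilt}: the full grid,
#'   rot fastest.
#' @examples
#' nrow(angleGrid(0, 360, 5, 90, 90, 5))  # 72 rotations at one tilt
#' @export
angleGrid <- function(rot0 = 0, rotF = 360, rotStep = 5,
                      tilt0 = 0, tiltF = 180, tiltStep = 5) {
  if (rotStep <= 0 || tiltStep <= 0) stop("step sizes must be positive")
  if (rotF <= rot0) stop("rotF must exceed rot0")
  if (tiltF < tilt0) stop("tiltF must not be below tilt0")
  nrot <- floor((rotF - rot0) / rotStep)
  if (nrot < 1L) stop("empty rotation grid")
  rots <- rot0 + rotStep * (seq_len(nrot) - 1L)
  tilts <- seq(tilt0, tiltF, by = tiltStep)
  expand.grid(rot = rots, tilt = tilts, KEEP.OUT.ATTRS = FALSE)
}

#' Orthographic projection of a phantom volume
#'
#' Line-integral (parallel-beam) projection along the viewing axis defined
#' by \code{(rot, tilt)}: the volume is resampled trilinearly along rays and
#' summed, so total intensity is conserved up to edge clipping.
#' \code{tilt = 0} is the top view (for \code{rot = 0} exactly the sum of
#' the grid along its depth axis); \code{tilt = 90} the side view.
#'
#' @param vol a phantom volume from [makePhantom()].
#' @param rot,tilt viewing angles in degrees.
#' @return an n x n numeric matrix.
#' @export
projectVolume <- function(vol, rot = 0, tilt = 0) {
  den <- vol$density
  n <- dim(den)[1L]
  if (rot %% 360 == 0 && tilt %% 360 == 0) {
    return(apply(den, c(1L, 2L), sum))      # exact top view
  }
  ctr <- (n + 1) / 2
  a <- rot * pi / 180; b <- tilt * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3L, 3L)
  M <- Rz %*% Ry                            # view frame -> volume frame
  ax <- seq_len(n) - ctr
  g <- expand.grid(y = ax, x = ax)
  out <- numeric(n * n)
  for (t in ax) {
    # view coords (x, y, t) -> volume coords; axes of M are (x, y, z)
    px <- M[1L, 1L] * g$x + M[1L, 2L] * g$y + M[1L, 3L] * t
    py <- M[2L, 1L] * g$x + M[2L, 2L] * g$y + M[2L, 3L] * t
    pz <- M[3L, 1L] * g$x + M[3L, 2L] * g$y + M[3L, 3L] * t
    out <- out + trilinear(den, py + ctr, px + ctr, pz + ctr)
  }
  matrix(out, n, n)
}

# Trilinear interpolation into a 3D array at fractional [i, j, k]
# coordinates; zero outside the support.
trilinear <- function(den, ii, jj, kk) {
  n <- dim(den)
  out <- numeric(length(ii))
  ok <- ii >= 1 & ii <= n[1L] & jj >= 1 & jj <= n[2L] & kk >= 1 & kk <= n[3L]
  if (!any(ok)) return(out)
  i <- ii[ok]; j <- jj[ok]; k <- kk[ok]
  i0 <- pmin(floor(i), n[1L] - 1L); fi <- i - i0
  j0 <- pmin(floor(j), n[2L] - 1L); fj <- j - j0
  k0 <- pmin(floor(k), n[3L] - 1L); fk <- k - k0
  s12 <- n[1L] * n[2L]
  base <- (k0 - 1) * s12 + (j0 - 1) * n[1L] + i0   # index of (i0, j0, k0)
  v <- (1 - fi) * (1 - fj) * (1 - fk) * den[base] +
       fi       * (1 - fj) * (1 - fk) * den[base + 1] +
       (1 - fi) * fj       * (1 - fk) * den[base + n[1L]] +
       fi       * fj       * (1 - fk) * den[base + n[1L] + 1] +
       (1 - fi) * (1 - fj) * fk       * den[base + s12] +
       fi       * (1 - fj) * fk       * den[base + s12 + 1] +
       (1 - fi) * fj       * fk       * den[base + s12 + n[1L]] +
       fi       * fj       * fk       * den[base + s12 + n[1L] + 1]
  out[ok] <- v
  out
}

#' Inject noise into an image at a target SNR
#'
#' SNR is defined as \code{var(signal) / var(noise)} (the usual convention
#' in cryo-EM simulation work); the injected noise is scaled so that
#' \code{var(noise) = var(img) / snr}. White Gaussian noise by default, or a
#' seeded random patch from \code{noiseBank} (structured noise) when given.
#'
#' @param img numeric matrix (the clean signal).
#' @param snr positive SNR, or \code{Inf} for no noise.
#' @param seed integer seed; the same seed yields the same noisy image.
#' @param noiseBank optional [ParticleStack-class] of noise patches matching
#'   \code{dim(img)}.
#' @return the noisy image.
#' @export
addNoise <- function(img, snr, seed, noiseBank = NULL) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0) {
    stop("snr must be a positive number (or Inf)")
  }
  if (is.infinite(snr)) return(img)
  targetSd <- sqrt(stats::var(as.vector(img)) / snr)
  withSeed(seed, function() {
    noise <- if (is.null(noiseBank)) {
      matrix(stats::rnorm(length(img)), nrow(img), ncol(img))
    } else {
      k <- sample.int(nImages(noiseBank), 1L)
      p <- getImage(noiseBank, k)
      if (!all(dim(p) == dim(img))) stop("noise bank patch size mismatch")
      (p - mean(p)) / stats::sd(as.vector(p))
    }
    img + noise * targetSd
  })
}

#' Generate a bank of structured (coloured) noise patches
#'
#' Gaussian white noise low-pass filtered at seeded random bandwidths,
#' emulating the spatially correlated background of real micrographs.
#'
#' @param n patch side length (even).
#' @param count number of patches.
#' @param seed integer seed.
#' @return a [ParticleStack-class] of \code{count} patches.
#' @export
makeNoiseBank <- function(n, count, seed) {
  imgs <- withSeed(seed, function() {
    lapply(seq_len(count), function(k) {
      sig <- stats::runif(1, 0.5, 2.5)
      p <- blurImage(matrix(stats::rnorm(n * n), n, n), sig)
      (p - mean(p)) / stats::sd(as.vector(p))
    })
  })
  ParticleStack(imgs)
}

#' Default dataset configuration
#'
#' The default values are the simulation protocol of the study conditions:
#' 11 classes of 100 images each per phantom (1100 projections per
#' structure), 104 x 104 pixels at 1.34 A/px, rot/tilt stepped at 5 degrees
#' with classes drawn as 11 distinct rotation angles at a fixed tilt, random
#' in-plane rotation per image, SNR 0.6, and a 1800/200/900-of-2900-style
#' train/val/test split.
#'
#' @param ... overrides for any configuration field.
#' @return a named list of configuration values.
#' @export
datasetConfig <- function(...) {
  cfg <- list(
    n = 104L, nPhantoms = 1L, kBlobs = 8L, pixelSize = 1.34,
    classes = 11L, perClass = 100L,
    rot0 = 0, rotF = 360, rotStep = 5, tilt = 90,
    psiRange = c(0, 360), shiftMax = 0, snr = 0.6,
    noiseType = "gaussian", noiseBankSize = 64L,
    split = c(train = 1800, val = 200, test = 900) / 2900,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Build a labelled synthetic particle dataset
#'
#' For every phantom, \code{classes} projection directions are taken from
#' the 5-degree rotation grid at the configured tilt; each class contributes
#' \code{perClass} images sharing that projection and differing by a random
#' in-plane rotation (and optional shift), with noise injected at the
#' configured SNR. Class ids are global across phantoms.
#'
#' @param cfg a configuration list from [datasetConfig()].
#' @param phantoms optional list of phantoms (from [makePhantom()]);
#'   generated from \code{cfg$seed} when omitted.
#' @return list with \code{stack} (a [ParticleStack-class]) and
#'   \code{metadata} (data.frame with id, class, rot, tilt, psi, dx, dy,
#'   snr, split): full per-image ground truth.
#' @export
buildDataset <- function(cfg = datasetConfig(), phantoms = NULL) {
  if (cfg$classes * cfg$perClass < 1L) stop("classes x perClass must be >= 1")
  grid <- angleGrid(cfg$rot0, cfg$rotF, cfg$rotStep, cfg$tilt, cfg$tilt,
                    cfg$rotStep)
  if (cfg$classes > nrow(grid)) stop("more classes than grid directions")
  sel <- round(seq(1L, nrow(grid), length.out = cfg$classes))
  if (is.null(phantoms)) {
    # multiple phantoms emulate *distinct* macromolecules: reject a draw
    # whose reference view is too similar to an already accepted phantom
    # (real structures used in such protocols are clearly distinct)
    phantoms <- list()
    seenViews <- list()
    for (p in seq_len(cfg$nPhantoms)) {
      for (attempt in 0:9) {
        pSeed <- if (attempt == 0L) childSeed(cfg$seed, 1000 + p) else
          childSeed(cfg$seed, 1000 + p, 100 * attempt)
        ph <- makePhantom(pSeed, n = cfg$n, kBlobs = cfg$kBlobs,
                          pixelSize = cfg$pixelSize)
        v <- projectVolume(ph, grid$rot[sel[1L]], grid$tilt[sel[1L]])
        similar <- any(vapply(seenViews, function(w) {
          stats::cor(as.vector(v), as.vector(w)) > 0.7
        }, logical(1L)))
        if (!similar) break
      }
      if (similar) stop("could not draw a distinct phantom in 10 attempts")
      phantoms[[p]] <- ph
      seenViews[[p]] <- v
    }
  }
  bank <- if (identical(cfg$noiseType, "bank")) {
    makeNoiseBank(cfg$n, cfg$noiseBankSize, childSeed(cfg$seed, 77))
  } else NULL
  imgs <- vector("list", length(phantoms) * cfg$classes * cfg$perClass)
  meta <- vector("list", length(imgs))
  idx <- 0L
  for (p in seq_along(phantoms)) {
    for (ci in seq_len(cfg$classes)) {
      rot <- grid$rot[sel[ci]]; tilt <- grid$tilt[sel[ci]]
      base <- projectVolume(phantoms[[p]], rot, tilt)
      classId <- (p - 1L) * cfg$classes + ci - 1L
      for (m in seq_len(cfg$perClass)) {
        idx <- idx + 1L
        s <- childSeed(cfg$seed, classId, m)
        draw <- withSeed(s, function() {
          list(psi = stats::runif(1, cfg$psiRange[1L], cfg$psiRange[2L]),
               dx = if (cfg$shiftMax > 0) {
                 stats::runif(1, -cfg$shiftMax, cfg$shiftMax)
               } else 0,
               dy = if (cfg$shiftMax > 0) {
                 stats::runif(1, -cfg$shiftMax, cfg$shiftMax)
               } else 0)
        })
        img <- if (draw$psi != 0) {
          rotateImage(base, draw$psi, fill = 0)
        } else base
        if (draw$dx != 0 || draw$dy != 0) {
          img <- translateImage(img, draw$dx, draw$dy, fill = 0)
        }
        img <- addNoise(img, cfg$snr, childSeed(s, 5), noiseBank = bank)
        imgs[[idx]] <- img
        meta[[idx]] <- data.frame(
          id = sprintf("p%02d_c%03d_%04d", p, classId, m),
          class = classId, rot = rot, tilt = tilt, psi = draw$psi,
          dx = draw$dx, dy = draw$dy, snr = cfg$snr,
          stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  nTot <- nrow(metadata)
  splits <- withSeed(childSeed(cfg$seed, 99), function() {
    sample(rep(names(cfg$split),
               diff(round(cumsum(c(0, cfg$split)) * nTot))))
  })
  metadata$split <- splits
  stack <- ParticleStack(imgs, pixelSize = cfg$pixelSize, ids = metadata$id)
  metadata <- metadata[order(metadata$id, method = "radix"), ]
  rownames(metadata) <- NULL
  validateMetadata(metadata, stack)
  list(stack = stack, metadata = metadata, phantoms = phantoms)
}

#' Pick a projection view suitable for rotation-recovery experiments
#'
#' Scans candidate (rot, tilt) directions and returns the one whose
#' projection has the lowest in-plane rotational self-correlation; a view
#' of an asymmetric phantom can still be nearly rotationally symmetric,
#' and rotation recovery is only well-posed on an asymmetric view.
#'
#' @param vol a phantom from [makePhantom()].
#' @param candidates data.frame of rot/tilt candidates (defaults to a
#'   coarse grid over the sphere).
#' @return list with \code{rot}, \code{tilt}, \code{selfCorr} and
#'   \code{image} (the projection).
#' @export
chooseAsymmetricView <- function(vol, candidates = NULL) {
  if (is.null(candidates)) {
    candidates <- expand.grid(rot = c(0, 40, 80, 120, 200, 280),
                              tilt = c(30, 60, 90, 120))
  }
  best <- NULL
  for (i in seq_len(nrow(candidates))) {
    p <- projectVolume(vol, candidates$rot[i], candidates$tilt[i])
    sc <- selfCorrMax(p)
    if (is.null(best) || sc < best$selfCorr) {
      best <- list(rot = candidates$rot[i], tilt = candidates$tilt[i],
                   selfCorr = sc, image = p)
    }
    if (best$selfCorr < 0.5) break
  }
  best
}
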