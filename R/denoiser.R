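# Adversarially trained particle denoiser.
#
# Generator: convolution block (stride-2 downsampling), residual blocks,
# sub-pixel convolution block (pixel shuffle) back to full resolution —
# input and output shapes are equal. Discriminator: five convolution
# layers with batch normalisation and leaky rectifiers, pooled to a single
# real/fake logit. The training loss is L1 reconstruction against the
# clean target plus a small non-saturating adversarial term.

buildGenerator <- function(width = 32L, nRes = 4L) {
  c(list(nnConv(1L, width, 3L), nnAct("lrelu"),
         nnConv(width, width, 3L, stride = 2L), nnAct("lrelu")),
    unlist(lapply(seq_len(nRes), function(i) {
      list(nnResBlock(width, width, 1L))
    }), recursive = FALSE),
    list(nnConv(width, 4L * width, 3L), nnPixelShuffle(2L),
         nnAct("lrelu"), nnConv(width, 1L, 3L)))
}

buildDiscriminator <- function(width = 16L) {
  list(nnConv(1L, width, 3L, stride = 2L), nnAct("lrelu"),
       nnConv(width, 2L * width, 3L, stride = 2L), nnBN(2L * width),
       nnAct("lrelu"),
       nnConv(2L * width, 4L * width, 3L, stride = 2L), nnBN(4L * width),
       nnAct("lrelu"),
       nnConv(4L * width, 4L * width, 3L), nnBN(4L * width),
       nnAct("lrelu"),
       nnConv(4L * width, 1L, 3L), nnGAP())
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

stackBatch <- function(stack, idx) {
  n <- imageSide(stack)
  x <- array(0, c(1L, n, n, length(idx)))
  for (j in seq_along(idx)) x[1L, , , j] <- getImage(stack, idx[j])
  x
}

#' Train the adversarial denoiser
#'
#' Paired training: \code{noisy} and \code{clean} must hold the same
#' particles in the same order (the simulator provides such pairs at any
#' SNR). Both stacks are normalised per image before training; the model
#' learns on (and denoises to) normalised intensity scale.
#'
#' @param noisy,clean paired [ParticleStack-class] objects, equal shapes.
#' @param epochs training epochs.
#' @param batch mini-batch size.
#' @param lr generator/discriminator learning rate (SGD + momentum).
#' @param lambdaAdv weight of the adversarial term (0 disables the
#'   discriminator updates entirely).
#' @param width generator base width; \code{nRes} residual blocks.
#' @param nRes number of residual blocks.
#' @param seed integer seed; training is deterministic per seed.
#' @param verbose print per-epoch losses.
#' @return a [DenoiserModel-class].
#' @export
trainDenoiser <- function(noisy, clean, epochs = 20L, batch = 16L,
                          lr = 0.01, lambdaAdv = 0.01, width = 32L,
                          nRes = 4L, seed = 1L, verbose = FALSE) {
  if (nImages(noisy) != nImages(clean) ||
      imageSide(noisy) != imageSide(clean)) {
    stop("noisy/clean stacks must pair up (same count and size)")
  }
  if (nImages(noisy) < 2L) stop("need at least two training pairs")
  noisy <- preprocessStack(noisy, mask = FALSE)
  clean <- preprocessStack(clean, mask = FALSE)
  N <- nImages(noisy)
  batch <- min(batch, N)
  G <- withSeed(childSeed(seed, 41), function() buildGenerator(width, nRes))
  D <- withSeed(childSeed(seed, 42), function() buildDiscriminator())
  hist <- data.frame(epoch = integer(0), recon = numeric(0),
                     adv = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- withSeed(childSeed(seed, 43, ep), function() sample.int(N))
    nb <- ceiling(N / batch)
    rsum <- 0; asum <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * batch + 1L):min(bi * batch, N)]
      x <- stackBatch(noisy, idx)
      y <- stackBatch(clean, idx)
      B <- length(idx)
      out <- netForward(G, x, train = TRUE)
      advLoss <- 0
      dAdv <- 0
      if (lambdaAdv > 0) {
        # discriminator step (generator output detached)
        lr_real <- netForward(D, y, train = TRUE)
        dReal <- matrix(-sigmoid(-lr_real) / B, 1L)
        netBackward(D, dReal)
        gReal <- lapply(netParamLayers(D), function(L) {
          pf <- .paramFields[[L$type]]
          lapply(pf, get, envir = L)
        })
        lr_fake <- netForward(D, out, train = TRUE)
        dFake <- matrix(sigmoid(lr_fake) / B, 1L)
        netBackward(D, dFake)
        # accumulate the real-pass gradients saved above
        pls <- netParamLayers(D)
        for (li in seq_along(pls)) {
          pf <- .paramFields[[pls[[li]]$type]]
          for (pi in seq_along(pf)) {
            cur <- get(pf[[pi]], envir = pls[[li]])
            assign(pf[[pi]], cur + gReal[[li]][[pi]], envir = pls[[li]])
          }
        }
        sgdStep(list(D), lr, momentum = 0.9)
        # generator adversarial gradient through a fresh D pass
        lg <- netForward(D, out, train = TRUE)
        advLoss <- mean(softplus(-lg))
        dAdv <- netBackward(D, matrix(-sigmoid(-lg) * lambdaAdv / B, 1L))
      }
      recon <- mean(abs(out - y))
      dOut <- sign(out - y) / length(out) + dAdv
      netBackward(G, dOut)
      sgdStep(list(G), lr, momentum = 0.9)
      rsum <- rsum + recon
      asum <- asum + advLoss
    }
    hist <- rbind(hist, data.frame(epoch = ep, recon = rsum / nb,
                                   adv = asum / nb))
    if (verbose) message(sprintf("denoiser epoch %3d  L1 %.5f  adv %.4f",
                                 ep, rsum / nb, asum / nb))
  }
  methods::new("DenoiserModel", generator = G, discriminator = D,
               history = hist, trained = TRUE, seed = as.integer(seed))
}

#' Denoise a particle stack
#'
#' Per-image generator inference (deterministic, evaluation mode). Images
#' are normalised on the way in; the output is returned on the normalised
#' scale rescaled back to each input's original mean and variance.
#'
#' @param stack a [ParticleStack-class].
#' @param model a trained [DenoiserModel-class].
#' @param batch inference batch size.
#' @return a [ParticleStack-class] of denoised images.
#' @export
denoiseStack <- function(stack, model, batch = 32L) {
  stopifnot(methods::is(model, "DenoiserModel"))
  if (!model@trained) stop("denoiser model is untrained")
  N <- nImages(stack)
  out <- stack@images
  for (b0 in seq(1L, N, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, N)
    n <- imageSide(stack)
    x <- array(0, c(1L, n, n, length(idx)))
    mu <- numeric(length(idx)); sdv <- numeric(length(idx))
    for (j in seq_along(idx)) {
      im <- getImage(stack, idx[j])
      mu[j] <- mean(im)
      sdv[j] <- stats::sd(as.vector(im))
      if (sdv[j] == 0) sdv[j] <- 1
      x[1L, , , j] <- (im - mu[j]) / sdv[j]
    }
    y <- netForward(model@generator, x, train = FALSE)
    for (j in seq_along(idx)) {
      out[, , idx[j]] <- y[1L, , , j] * sdv[j] + mu[j]
    }
  }
  ParticleStack(out, pixelSize = pixelSize(stack), ids = particleIds(stack))
}
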