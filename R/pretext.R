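# Stage 1: contrastive (instance-discrimination) representation learning.
#
# Each image is turned into two stochastically augmented views; the encoder
# f maps a view to a 512-dimensional feature h, the projection head g to a
# unit-norm 128-dimensional feature z, and the normalised-temperature
# cross-entropy loss pulls the two views of one image together against the
# rest of the batch. After training, g is set aside and h feeds the
# clustering stage; nearest neighbours mined on z seed its consistency loss.

#' Pretext training configuration
#'
#' \code{preset = "desk"} is sized for CPU work (small residual backbone,
#' 24 px inputs, batch 64, learning rate 0.1, at most 50 epochs);
#' \code{preset = "paper"} is the full-scale protocol (18-layer residual
#' backbone, 128 px inputs, SGD at initial learning rate 0.4 with cosine
#' decay, batch 128, 500 epochs).
#'
#' @param preset \code{"desk"} or \code{"paper"}.
#' @param ... overrides for any field.
#' @return named list of settings.
#' @export
pretextConfig <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(backbone = "small", width = 12L, inputSize = 24L, batch = 64L,
         epochs = 30L, lr = 0.1, momentum = 0.9, weightDecay = 5e-4,
         tau = 0.5, hDim = 512L, zDim = 128L, seed = 1L)
  } else {
    list(backbone = "resnet18", width = 64L, inputSize = 128L, batch = 128L,
         epochs = 500L, lr = 0.4, momentum = 0.9, weightDecay = 5e-4,
         tau = 0.5, hDim = 512L, zDim = 128L, seed = 1L)
  }
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate an augmented view pair
#'
#' Each view is an independently drawn random resized crop (area scale
#' 0.6-1.0), random horizontal flip, random rotation (0-360 degrees) and
#' intensity jitter (brightness, contrast, gamma — the grayscale stand-in
#' for recolouring), with an occasional Gaussian blur, resampled to
#' \code{size x size} and normalised to zero mean, unit variance.
#' Deterministic per seed. With \code{enabled = FALSE} both views are the
#' plain resized (and normalised) image.
#'
#' @param img square numeric matrix.
#' @param seed integer seed.
#' @param size output side length in pixels.
#' @param enabled set to \code{FALSE} to disable all stochastic transforms.
#' @return list with matrices \code{xi}, \code{xj}.
#' @export
augmentPair <- function(img, seed, size = 24L, enabled = TRUE) {
  n <- nrow(img)
  if (!enabled) {
    v <- normalizeImage(resampleWindow(img, (n + 1) / 2, (n + 1) / 2, n, size))
    return(list(xi = v, xj = v))
  }
  withSeed(seed, function() {
    list(xi = augmentOnce(img, size), xj = augmentOnce(img, size))
  })
}

augmentOnce <- function(img, size) {
  n <- nrow(img)
  side <- n * sqrt(stats::runif(1, 0.6, 1))
  half <- side / 2
  lo <- min(half + 0.5, (n + 1) / 2)
  hi <- max(n + 0.5 - half, (n + 1) / 2)
  rc <- stats::runif(1, lo, hi)
  cc <- stats::runif(1, lo, hi)
  v <- resampleWindow(img, rc, cc, side, size,
                      degrees = stats::runif(1, 0, 360),
                      flip = stats::runif(1) < 0.5)
  # intensity jitter: contrast/brightness about the image statistics, then
  # gamma on the min-max range
  m <- mean(v); s <- stats::sd(as.vector(v))
  v <- m + (v - m) * (1 + stats::runif(1, -0.4, 0.4)) +
    stats::runif(1, -0.4, 0.4) * s
  rng <- range(v)
  if (rng[2L] > rng[1L]) {
    u <- (v - rng[1L]) / (rng[2L] - rng[1L])
    v <- u^stats::runif(1, 0.7, 1.4) * (rng[2L] - rng[1L]) + rng[1L]
  }
  if (stats::runif(1) < 0.3) v <- blurImage(v, stats::runif(1, 0.3, 1))
  normalizeImage(v)
}

#' Normalised-temperature cross-entropy (contrastive) loss
#'
#' \code{z} holds 2B unit-norm embeddings in B consecutive pairs (rows 1-2
#' are the two views of image 1, and so on). For each anchor the positive is
#' its partner view; the negatives are the other 2B-2 embeddings; the loss
#' is the mean over the 2B anchors of the softmax cross-entropy on cosine
#' similarities scaled by \code{tau}. With B = 1 there are no negatives and
#' the loss is exactly 0.
#'
#' @param z numeric matrix, 2B x d, rows unit-norm.
#' @param tau temperature (> 0).
#' @return scalar loss (non-negative).
#' @export
ntXentLoss <- function(z, tau = 0.5) {
  ntXentGrad(t(z), tau)$loss
}

# Loss and gradient, columns-as-samples layout (d x 2B) as used in training.
ntXentGrad <- function(zc, tau) {
  m <- ncol(zc)
  if (m %% 2L != 0L || m < 2L) stop("z must hold an even number of rows >= 2")
  nrm <- colSums(zc^2)
  if (any(nrm < 1e-12)) stop("zero-norm embedding")
  S <- crossprod(zc) / tau
  diag(S) <- -Inf
  partner <- ifelse(seq_len(m) %% 2L == 1L, seq_len(m) + 1L, seq_len(m) - 1L)
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)
  denom <- rowSums(E)
  P <- E / denom
  loss <- -mean(S[cbind(seq_len(m), partner)] - mx - log(denom))
  Y <- matrix(0, m, m)
  Y[cbind(seq_len(m), partner)] <- 1
  G <- (P - Y) / m
  dz <- (zc %*% G + zc %*% t(G)) / tau   # S is used symmetrically
  list(loss = loss, dz = dz)
}

#' Train the contrastive encoder
#'
#' SGD with momentum and cosine learning-rate decay over augmented view
#' pairs; fully deterministic given \code{cfg$seed}. When \code{labels} are
#' supplied (simulation), a per-epoch KNN validation accuracy curve is
#' recorded on the current features.
#'
#' @param stack a [ParticleStack-class] of (preprocessed) particles.
#' @param cfg configuration from [pretextConfig()].
#' @param labels optional integer ground-truth labels for the KNN curve.
#' @param verbose print per-epoch progress.
#' @return an [EncoderModel-class].
#' @export
trainPretext <- function(stack, cfg = pretextConfig(), labels = NULL,
                         verbose = FALSE) {
  N <- nImages(stack)
  if (N < 2L) stop("need at least two images")
  batch <- min(cfg$batch, N)
  model <- withSeed(childSeed(cfg$seed, 1), function() {
    list(backbone = buildBackbone(cfg$backbone, cfg$width, cfg$hDim),
         head = buildProjectionHead(cfg$hDim, cfg$zDim))
  })
  lossCurve <- numeric(cfg$epochs)
  knnCurve <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    lr <- cosineLr(cfg$lr, ep, cfg$epochs)
    ord <- withSeed(childSeed(cfg$seed, 2, ep), function() sample.int(N))
    nb <- ceiling(N / batch)
    lsum <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * batch + 1L):min(bi * batch, N)]
      B <- length(idx)
      x <- array(0, c(1L, cfg$inputSize, cfg$inputSize, 2L * B))
      for (j in seq_len(B)) {
        pr <- augmentPair(getImage(stack, idx[j]),
                          childSeed(cfg$seed, 3, ep, bi, j), cfg$inputSize)
        x[1L, , , 2L * j - 1L] <- pr$xi
        x[1L, , , 2L * j] <- pr$xj
      }
      h <- netForward(model$backbone, x, train = TRUE)
      z <- netForward(model$head, h, train = TRUE)
      lg <- ntXentGrad(z, cfg$tau)
      dh <- netBackward(model$head, lg$dz)
      netBackward(model$backbone, dh)
      sgdStep(list(model$backbone, model$head), lr,
              momentum = cfg$momentum, weightDecay = cfg$weightDecay)
      lsum <- lsum + lg$loss
    }
    lossCurve[ep] <- lsum / nb
    if (!is.null(labels)) {
      emb <- extractFeaturesNet(stack, model, cfg$inputSize)
      knnCurve <- c(knnCurve, knnValidate(emb$z, labels,
                                          K = min(5L, N - 1L)))
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f%s", ep, lossCurve[ep],
                      if (!is.null(labels)) {
                        sprintf("  knn %.3f", utils::tail(knnCurve, 1L))
                      } else ""))
    }
  }
  methods::new("EncoderModel", backbone = model$backbone, head = model$head,
               inputSize = as.integer(cfg$inputSize),
               temperature = cfg$tau, lossCurve = lossCurve,
               knnCurve = knnCurve, trained = TRUE,
               seed = as.integer(cfg$seed))
}

# Shared inference path: plain resize + normalise, eval-mode forward.
extractFeaturesNet <- function(stack, model, inputSize, batch = 128L) {
  N <- nImages(stack)
  n <- imageSide(stack)
  hList <- list(); zList <- list()
  for (b0 in seq(1L, N, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, N)
    x <- array(0, c(1L, inputSize, inputSize, length(idx)))
    for (j in seq_along(idx)) {
      x[1L, , , j] <- normalizeImage(resampleWindow(
        getImage(stack, idx[j]), (n + 1) / 2, (n + 1) / 2, n, inputSize))
    }
    h <- netForward(model$backbone, x, train = FALSE)
    z <- netForward(model$head, h, train = FALSE)
    hList[[length(hList) + 1L]] <- h
    zList[[length(zList) + 1L]] <- z
  }
  list(h = t(do.call(cbind, hList)), z = t(do.call(cbind, zList)))
}

#' Extract features for a stack
#'
#' Deterministic, augmentation-free inference: each image is resized to the
#' model input, normalised, and passed through the backbone and projection
#' head.
#'
#' @param stack a [ParticleStack-class].
#' @param model a trained [EncoderModel-class].
#' @return an [EmbeddingSet-class] with \code{h} (N x 512) and unit-norm
#'   \code{z} (N x 128); the neighbour table is empty until
#'   [mineNeighbors()] is called.
#' @export
extractFeatures <- function(stack, model) {
  stopifnot(methods::is(model, "EncoderModel"))
  if (!model@trained) stop("model is untrained")
  e <- extractFeaturesNet(stack, list(backbone = model@backbone,
                                      head = model@head), model@inputSize)
  methods::new("EmbeddingSet", h = e$h, z = e$z,
               neighbors = matrix(integer(0), nrow(e$h), 0L),
               ids = particleIds(stack))
}

#' Mine K nearest neighbours by cosine similarity
#'
#' Exhaustive pairwise search over the projected features \code{z} (or any
#' feature matrix), excluding self-matches; ties broken towards the lower
#' index.
#'
#' @param x an [EmbeddingSet-class] or a numeric feature matrix
#'   (rows = samples).
#' @param K neighbours per sample, \code{K < N}.
#' @return for an EmbeddingSet input, the same object with its neighbour
#'   table filled; for a matrix, the N x K integer neighbour matrix.
#' @export
mineNeighbors <- function(x, K) {
  Z <- if (methods::is(x, "EmbeddingSet")) x@z else x
  N <- nrow(Z)
  if (K >= N) stop("K must be smaller than the number of samples")
  Zn <- Z / sqrt(rowSums(Z^2))
  S <- Zn %*% t(Zn)
  diag(S) <- -Inf
  nb <- t(apply(S, 1L, function(r) {
    order(-r, seq_along(r))[seq_len(K)]    # stable: ties to lower index
  }))
  nb <- matrix(as.integer(nb), N, K)
  if (methods::is(x, "EmbeddingSet")) {
    methods::initialize(x, neighbors = nb)
  } else nb
}

#' KNN validation accuracy of labelled features
#'
#' Majority-vote K-nearest-neighbour classification by cosine similarity
#' (self excluded); a sample counts as a hit if its true label is among the
#' \code{topM} highest-voted classes. Only meaningful on simulated data,
#' where ground truth exists.
#'
#' @param x feature matrix (rows = samples) or [EmbeddingSet-class]
#'   (uses \code{z}).
#' @param labels ground-truth labels, one per sample.
#' @param K neighbours to vote, \code{K < N}.
#' @param topM hits are counted within the top-M voted classes.
#' @return accuracy in [0, 1].
#' @export
knnValidate <- function(x, labels, K = 5L, topM = 1L) {
  Z <- if (methods::is(x, "EmbeddingSet")) x@z else x
  N <- nrow(Z)
  if (length(labels) != N) stop("labels must match the sample count")
  nb <- mineNeighbors(Z, K)
  labs <- as.character(labels)
  hits <- vapply(seq_len(N), function(i) {
    votes <- sort(table(labs[nb[i, ]]), decreasing = TRUE)
    top <- names(votes)[seq_len(min(topM, length(votes)))]
    labs[i] %in% top
  }, logical(1L))
  mean(hits)
}
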