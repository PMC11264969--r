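# Stage 2: learnable clustering over the pretext encoder.
#
# A linear head maps the 512-dimensional backbone feature to C logits; the
# softmax output is trained so that each sample and its mined nearest
# neighbours receive consistent probability vectors, with an entropy term
# on the batch-mean probabilities that rewards balanced clusters. A
# self-labelling phase then fine-tunes on confident predictions
# (max probability above a threshold, 0.95 by default).

#' Clustering-stage configuration
#'
#' @param preset \code{"desk"} (CPU scale: 20 epochs, batch 64) or
#'   \code{"paper"} (full scale).
#' @param ... overrides for any field.
#' @return named list of settings.
#' @export
clusterConfig <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(nClasses = 11L, epochs = 20L, batch = 64L, lr = 0.05,
         momentum = 0.9, weightDecay = 5e-4, lambda = 5, nHeads = 5L,
         backboneLrFrac = 0.1, augment = TRUE, selfLabelLrFrac = 0.02,
         selfLabelRounds = 2L, selfLabelEpochs = 2L, threshold = 0.95,
         seed = 1L)
  } else {
    list(nClasses = 11L, epochs = 100L, batch = 128L, lr = 0.05,
         momentum = 0.9, weightDecay = 5e-4, lambda = 5, nHeads = 10L,
         backboneLrFrac = 0.1, augment = TRUE, selfLabelLrFrac = 0.02,
         selfLabelRounds = 4L, selfLabelEpochs = 5L, threshold = 0.95,
         seed = 1L)
  }
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Neighbour-consistency clustering loss
#'
#' \code{-mean(log <pAnchor, pNeighbor>)} over the given neighbours, minus
#' \code{lambda} times the entropy of \code{clusterMean}; inner products
#' below \code{1e-8} are clamped (with a warning) to keep the loss finite.
#'
#' @param pAnchor probability vector on the C-simplex.
#' @param pNeighbors list of probability vectors (the anchor's neighbours).
#' @param clusterMean mean probability vector of the batch/cluster.
#' @param lambda entropy weight (>= 0).
#' @return scalar loss.
#' @export
scanLoss <- function(pAnchor, pNeighbors, clusterMean, lambda = 5) {
  if (lambda < 0) stop("lambda must be >= 0")
  dots <- vapply(pNeighbors, function(p) sum(pAnchor * p), numeric(1L))
  if (any(dots < 1e-8)) {
    warning("inner product clamped at 1e-8")
    dots <- pmax(dots, 1e-8)
  }
  ent <- -sum(ifelse(clusterMean > 0, clusterMean * log(clusterMean), 0))
  -mean(log(dots)) - lambda * ent
}

# Batch loss + gradient w.r.t. logits. pA, pN: C x B softmax outputs of
# anchors and their sampled neighbours; the entropy term uses the anchor
# batch mean.
scanGrad <- function(logitA, logitN, lambda) {
  pA <- softmaxCols(logitA)
  pN <- softmaxCols(logitN)
  B <- ncol(pA)
  dots <- pmax(colSums(pA * pN), 1e-8)
  m <- rowMeans(pA)
  ent <- -sum(ifelse(m > 0, m * log(m), 0))
  loss <- -mean(log(dots)) - lambda * ent
  dpA <- -sweep(pN, 2L, B * dots, `/`)
  dpN <- -sweep(pA, 2L, B * dots, `/`)
  dpA <- dpA + lambda * (log(pmax(m, 1e-6)) + 1) / B
  list(loss = loss,
       dLogitA = softmaxBackCols(pA, dpA),
       dLogitN = softmaxBackCols(pN, dpN))
}

softmaxCols <- function(l) {
  e <- exp(sweep(l, 2L, apply(l, 2L, max)))
  sweep(e, 2L, colSums(e), `/`)
}

softmaxBackCols <- function(p, dp) {
  p * sweep(dp, 2L, colSums(dp * p))
}

newClusterModel <- function(encoder, nClasses, seed, nHeads = 1L) {
  heads <- lapply(seq_len(nHeads), function(k) {
    head <- withSeed(childSeed(seed, 11, k), function() {
      nnDense(512L, nClasses)
    })
    # small initial weights keep the initial output near-uniform; a
    # confident random head starves clusters before the entropy term acts
    head$W <- head$W * 0.1
    head
  })
  model <- methods::new("ClusterModel",
                        backbone = netClone(encoder@backbone),
                        headLayer = list(heads[[1L]]),
                        nClasses = as.integer(nClasses),
                        inputSize = encoder@inputSize,
                        lossCurve = numeric(0),
                        trained = FALSE, seed = as.integer(seed))
  list(model = model, heads = heads)
}

clusterBatchInput <- function(stack, idx, size, seed, augment) {
  x <- array(0, c(1L, size, size, length(idx)))
  n <- imageSide(stack)
  for (j in seq_along(idx)) {
    x[1L, , , j] <- if (augment) {
      withSeed(childSeed(seed, j), function() augmentOnce(
        getImage(stack, idx[j]), size))
    } else {
      normalizeImage(resampleWindow(getImage(stack, idx[j]),
                                    (n + 1) / 2, (n + 1) / 2, n, size))
    }
  }
  x
}

#' Train the clustering head (neighbour-consistency phase)
#'
#' Initialised from the stage-1 encoder weights; each step samples a batch
#' of anchors and, for every anchor, one of its mined neighbours, and
#' minimises the consistency-plus-entropy loss. The backbone is fine-tuned
#' at a fraction of the head learning rate.
#'
#' @param encoder a trained [EncoderModel-class].
#' @param stack the particle stack the neighbours were mined on.
#' @param neighbors N x K integer neighbour table (from [mineNeighbors()]).
#' @param cfg configuration from [clusterConfig()].
#' @param verbose print per-epoch progress.
#' @return a trained [ClusterModel-class].
#' @export
trainCluster <- function(encoder, stack, neighbors, cfg = clusterConfig(),
                         verbose = FALSE) {
  stopifnot(methods::is(encoder, "EncoderModel"))
  N <- nImages(stack)
  if (cfg$nClasses >= N) stop("need more samples than clusters")
  if (nrow(neighbors) != N) stop("neighbour table must cover all samples")
  nHeads <- if (is.null(cfg$nHeads)) 1L else cfg$nHeads
  built <- newClusterModel(encoder, cfg$nClasses, cfg$seed, nHeads)
  model <- built$model
  heads <- lapply(built$heads, list)          # each head is a 1-layer net
  batch <- min(cfg$batch, N)
  lossCurve <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- cosineLr(cfg$lr, ep, cfg$epochs)
    ord <- withSeed(childSeed(cfg$seed, 21, ep), function() sample.int(N))
    nb <- ceiling(N / batch)
    lsum <- 0
    for (bi in seq_len(nb)) {
      aIdx <- ord[((bi - 1L) * batch + 1L):min(bi * batch, N)]
      nIdx <- withSeed(childSeed(cfg$seed, 22, ep, bi), function() {
        vapply(aIdx, function(i) {
          neighbors[i, sample.int(ncol(neighbors), 1L)]
        }, integer(1L))
      })
      sA <- childSeed(cfg$seed, 23, ep, bi)
      xA <- clusterBatchInput(stack, aIdx, model@inputSize, sA, cfg$augment)
      xN <- clusterBatchInput(stack, nIdx, model@inputSize,
                              childSeed(sA, 1), cfg$augment)
      B <- length(aIdx)
      x <- array(c(xA, xN), c(1L, model@inputSize, model@inputSize, 2L * B))
      h <- netForward(model@backbone, x, train = TRUE)
      dh <- 0
      hl <- 0
      for (hd in heads) {
        logit <- netForward(hd, h, train = TRUE)
        g <- scanGrad(logit[, seq_len(B), drop = FALSE],
                      logit[, B + seq_len(B), drop = FALSE], cfg$lambda)
        dh <- dh + netBackward(hd, cbind(g$dLogitA, g$dLogitN)) / nHeads
        hl <- hl + g$loss / nHeads
      }
      netBackward(model@backbone, dh)
      clipGradients(c(heads, list(model@backbone)), 1)
      sgdStep(c(heads, list(model@backbone)), lr,
              momentum = cfg$momentum, weightDecay = cfg$weightDecay,
              lrScale = c(rep(1, nHeads), cfg$backboneLrFrac))
      lsum <- lsum + hl
    }
    lossCurve[ep] <- lsum / nb
    if (verbose) message(sprintf("cluster epoch %3d  mean head loss %.4f",
                                 ep, lossCurve[ep]))
  }
  # keep the head that minimises the training objective on the full data
  # (augmentation-free): the reference strategy against bad head optima
  feats <- clusterEvalFeatures(model, stack)
  headLoss <- vapply(heads, function(hd) {
    p <- softmaxCols(netForward(hd, feats, train = FALSE))
    cons <- 0
    K <- ncol(neighbors)
    for (k in seq_len(K)) {
      cons <- cons - mean(log(pmax(colSums(p * p[, neighbors[, k],
                                                 drop = FALSE]), 1e-8)))
    }
    m <- rowMeans(p)
    cons / K + cfg$lambda * sum(ifelse(m > 0, m * log(m), 0))
  }, numeric(1L))
  best <- which.min(headLoss)
  if (verbose) message(sprintf("selected head %d of %d (loss %.4f)", best,
                               nHeads, headLoss[best]))
  methods::initialize(model, headLayer = heads[[best]],
                      lossCurve = lossCurve, trained = TRUE)
}

# Augmentation-free features of the whole stack under the model backbone.
clusterEvalFeatures <- function(model, stack) {
  N <- nImages(stack)
  out <- NULL
  for (b0 in seq(1L, N, by = 128L)) {
    idx <- b0:min(b0 + 127L, N)
    x <- clusterBatchInput(stack, idx, model@inputSize, 0L,
                           augment = FALSE)
    h <- netForward(model@backbone, x, train = FALSE)
    out <- cbind(out, h)
  }
  out
}

#' Self-labelling with confidence-thresholded pseudo-labels
#'
#' Iterates: assign cluster probabilities; keep samples whose maximum
#' probability exceeds \code{threshold} as pseudo-labelled; fine-tune with
#' a cross-entropy loss on augmented views of the confident set, sampled
#' class-balanced to avoid collapse; repeat. If no sample clears the
#' threshold the input model is returned unchanged (with a message).
#'
#' @param model a trained [ClusterModel-class].
#' @param stack the particle stack.
#' @param threshold pseudo-label confidence threshold in (0, 1); a sample
#'   becomes a pseudo-label only when its probability exceeds it strictly.
#' @param cfg configuration from [clusterConfig()] (rounds/epochs/lr).
#' @param verbose print per-round progress.
#' @return the fine-tuned [ClusterModel-class].
#' @export
selfLabel <- function(model, stack, threshold = 0.95,
                      cfg = clusterConfig(), verbose = FALSE) {
  stopifnot(methods::is(model, "ClusterModel"))
  if (!model@trained) stop("cluster model is untrained")
  if (threshold <= 0 || threshold >= 1) {
    if (threshold == 1) {
      message("threshold 1: no pseudo-labels possible, model unchanged")
      return(model)
    }
    stop("threshold must lie in (0, 1)")
  }
  N <- nImages(stack)
  batch <- min(cfg$batch, N)
  for (round in seq_len(cfg$selfLabelRounds)) {
    asg <- assignClusters(model, stack, threshold = threshold)
    conf <- which(asg$pseudo)
    if (length(conf) == 0L) {
      message("no sample above the pseudo-label threshold; model unchanged")
      return(model)
    }
    byClass <- split(conf, asg$label[conf])
    lr <- cfg$lr * (if (is.null(cfg$selfLabelLrFrac)) 0.02 else cfg$selfLabelLrFrac)
    for (ep in seq_len(cfg$selfLabelEpochs)) {
      nb <- ceiling(length(conf) / batch)
      for (bi in seq_len(nb)) {
        s <- childSeed(cfg$seed, 31, round, ep, bi)
        idx <- withSeed(s, function() {
          # class-balanced: draw classes uniformly, then members
          cls <- sample(names(byClass), batch, replace = TRUE)
          vapply(cls, function(cl) {
            v <- byClass[[cl]]
            v[sample.int(length(v), 1L)]
          }, integer(1L), USE.NAMES = FALSE)
        })
        x <- clusterBatchInput(stack, idx, model@inputSize,
                               childSeed(s, 2), cfg$augment)
        # head-only fine-tuning: with a confident set this small, updating
        # the backbone overfits and starves clusters
        h <- netForward(model@backbone, x, train = FALSE)
        logit <- netForward(model@headLayer, h, train = TRUE)
        p <- softmaxCols(logit)
        yIdx <- asg$label[idx] + 1L
        Y <- matrix(0, model@nClasses, length(idx))
        Y[cbind(yIdx, seq_along(idx))] <- 1
        dLogit <- (p - Y) / length(idx)
        netBackward(model@headLayer, dLogit)
        clipGradients(list(model@headLayer), 1)
        sgdStep(list(model@headLayer), lr,
                momentum = cfg$momentum, weightDecay = cfg$weightDecay)
      }
    }
    if (verbose) message(sprintf("self-label round %d: %d pseudo-labels",
                                 round, length(conf)))
  }
  model
}

#' Assign cluster probabilities to a stack
#'
#' Deterministic, augmentation-free inference. Argmax ties break towards
#' the lowest class index; labels are 0-based to match simulator class ids.
#'
#' @param model a trained [ClusterModel-class].
#' @param stack a [ParticleStack-class].
#' @param threshold pseudo-label flag threshold (strictly-greater rule).
#' @return data.frame with \code{id}, \code{label} (0-based), \code{prob}
#'   (max probability), \code{pseudo} (flag), and one \code{p.<k>} column
#'   per class.
#' @export
assignClusters <- function(model, stack, threshold = 0.95) {
  stopifnot(methods::is(model, "ClusterModel"))
  if (!model@trained) stop("cluster model is untrained")
  N <- nImages(stack)
  size <- model@inputSize
  n <- imageSide(stack)
  probs <- matrix(0, model@nClasses, N)
  for (b0 in seq(1L, N, by = 128L)) {
    idx <- b0:min(b0 + 127L, N)
    x <- clusterBatchInput(stack, idx, size, 0L, augment = FALSE)
    h <- netForward(model@backbone, x, train = FALSE)
    probs[, idx] <- softmaxCols(netForward(model@headLayer, h,
                                           train = FALSE))
  }
  label <- apply(probs, 2L, which.max) - 1L   # which.max: lowest index wins
  mx <- probs[cbind(label + 1L, seq_len(N))]
  out <- data.frame(id = particleIds(stack), label = label, prob = mx,
                    pseudo = mx > threshold, stringsAsFactors = FALSE)
  pm <- t(probs)
  colnames(pm) <- paste0("p.", seq_len(model@nClasses) - 1L)
  cbind(out, as.data.frame(pm))
}
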