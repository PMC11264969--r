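# Minimal neural-network engine: the layers the pipeline's models need
# (convolution, batch normalisation, rectifiers, residual blocks, sub-pixel
# shuffle, dense, global average pooling, L2 normalisation), explicit
# backpropagation and SGD with momentum. Data layout is channels-first:
# activations are arrays [C, H, W, N]; dense activations are matrices
# [features, N]. Layers are environments so that caches and momentum
# buffers update in place; every gradient is verified against finite
# differences in the test suite.

newLayer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

heInit <- function(nOut, nIn, fanIn) {
  matrix(stats::rnorm(nOut * nIn, sd = sqrt(2 / fanIn)), nOut, nIn)
}

nnConv <- function(inC, outC, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  newLayer("conv", inC = inC, outC = outC, k = as.integer(k),
           stride = as.integer(stride), pad = as.integer(pad),
           W = heInit(outC, inC * k * k, inC * k * k), b = numeric(outC))
}

nnBN <- function(C, momentum = 0.1, eps = 1e-5) {
  newLayer("bn", C = C, gamma = rep(1, C), beta = numeric(C),
           rmean = numeric(C), rvar = rep(1, C),
           momentum = momentum, eps = eps)
}

nnAct <- function(kind = c("relu", "lrelu"), alpha = 0.2) {
  kind <- match.arg(kind)
  newLayer("act", kind = kind, alpha = alpha)
}

nnDense <- function(nIn, nOut) {
  newLayer("dense", W = heInit(nOut, nIn, nIn), b = numeric(nOut))
}

nnGAP <- function() newLayer("gap")

nnL2Norm <- function() newLayer("l2norm")

nnPixelShuffle <- function(r = 2L) newLayer("pixshuf", r = as.integer(r))

nnResBlock <- function(inC, outC, stride = 1L, actKind = "relu") {
  proj <- if (stride != 1L || inC != outC) {
    list(conv = nnConv(inC, outC, 1L, stride = stride, pad = 0L),
         bn = nnBN(outC))
  } else NULL
  newLayer("resblock",
           conv1 = nnConv(inC, outC, 3L, stride = stride),
           bn1 = nnBN(outC), act = nnAct(actKind),
           conv2 = nnConv(outC, outC, 3L), bn2 = nnBN(outC),
           proj = proj)
}

# ---- forward / backward ----------------------------------------------------

# im2col gather indices for one padded image, as an array (C, k, k, Ho,
# Wo), plus the per-image stride; cached per input geometry in the layer.
convPlan <- function(L, C, H, W, N) {
  key <- paste(C, H, W, N, sep = "x")
  if (identical(L$planKey, key)) return(L$plan)
  k <- L$k; s <- L$stride; p <- L$pad
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (W + 2L * p - k) %/% s + 1L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  rI <- outer(seq_len(k), s * (seq_len(Ho) - 1L), `+`)      # k x Ho
  cI <- outer(seq_len(k), s * (seq_len(Wo) - 1L), `+`)      # k x Wo
  m1 <- outer(seq_len(C), as.integer(C * (rI - 1L)), `+`)   # (c, kr, oh)
  m2 <- outer(as.vector(m1), as.integer(C * Hp * (cI - 1L)), `+`)
  idx <- array(m2, c(C, k, Ho, k, Wo))
  idx <- aperm(idx, c(1L, 2L, 4L, 3L, 5L))                  # c,kr,kc,oh,ow
  perImage <- C * Hp * Wp
  idxBig <- as.integer(outer(as.vector(idx),
                             perImage * (seq_len(N) - 1L), `+`))
  # per-slab row blocks (for the backward scatter) share the gather order
  dim(idx) <- c(C, k * k, Ho * Wo)
  plan <- list(Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, idxBig = idxBig,
               idxSlab = idx, perImage = perImage)
  L$plan <- plan
  L$planKey <- key
  plan
}

convForward <- function(L, x, train) {
  d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  k <- L$k; p <- L$pad
  pl <- convPlan(L, C, H, W, N)
  if (p > 0L) {
    P <- array(0, c(C, pl$Hp, pl$Wp, N))
    P[, p + seq_len(H), p + seq_len(W), ] <- x
  } else P <- x
  patches <- P[pl$idxBig]
  dim(patches) <- c(C * k * k, pl$Ho * pl$Wo * N)
  out <- L$W %*% patches + L$b
  if (train) L$cache <- list(patches = patches, dims = d)
  dim(out) <- c(L$outC, pl$Ho, pl$Wo, N)
  out
}

convBackward <- function(L, dout) {
  cc <- L$cache
  d <- cc$dims; C <- d[1L]; N <- d[4L]
  k <- L$k; p <- L$pad
  pl <- convPlan(L, C, d[2L], d[3L], N)
  Ho <- pl$Ho; Wo <- pl$Wo
  dim(dout) <- c(L$outC, Ho * Wo * N)
  L$gW <- tcrossprod(dout, cc$patches)
  L$gb <- rowSums(dout)
  dpatch <- crossprod(L$W, dout)
  dim(dpatch) <- c(C, k * k, Ho * Wo * N)
  dP <- numeric(pl$perImage * N)
  nOff <- pl$perImage * (seq_len(N) - 1L)
  slabLen <- C * Ho * Wo
  for (sl in seq_len(k * k)) {
    # within one slab every target cell is distinct, so an indexed add is
    # exact; slabs are accumulated sequentially
    ii <- as.integer(outer(as.vector(pl$idxSlab[, sl, ]), nOff, `+`))
    v <- dpatch[, sl, ]
    dP[ii] <- dP[ii] + as.vector(v)
  }
  dim(dP) <- c(C, pl$Hp, pl$Wp, N)
  L$cache <- NULL
  if (p > 0L) {
    dP[, p + seq_len(d[2L]), p + seq_len(d[3L]), , drop = FALSE]
  } else dP
}

bnForward <- function(L, x, train) {
  d <- dim(x)
  X <- matrix(x, d[1L])
  if (train) {
    m <- rowMeans(X)
    v <- rowMeans(X^2) - m^2
    L$rmean <- (1 - L$momentum) * L$rmean + L$momentum * m
    L$rvar <- (1 - L$momentum) * L$rvar + L$momentum * v
  } else {
    m <- L$rmean; v <- L$rvar
  }
  istd <- 1 / sqrt(v + L$eps)
  xhat <- (X - m) * istd
  if (train) L$cache <- list(xhat = xhat, istd = istd, d = d)
  array(L$gamma * xhat + L$beta, d)
}

bnBackward <- function(L, dout) {
  cc <- L$cache
  d <- cc$d
  dY <- matrix(dout, d[1L])
  xhat <- cc$xhat
  L$ggamma <- rowSums(dY * xhat)
  L$gbeta <- rowSums(dY)
  m <- ncol(dY)
  dxhat <- L$gamma * dY
  dX <- cc$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  L$cache <- NULL
  array(dX, d)
}

actForward <- function(L, x, train) {
  out <- if (L$kind == "relu") pmax(x, 0) else ifelse(x > 0, x, L$alpha * x)
  if (train) L$cache <- x
  out
}

actBackward <- function(L, dout) {
  x <- L$cache
  L$cache <- NULL
  if (L$kind == "relu") dout * (x > 0) else dout * ifelse(x > 0, 1, L$alpha)
}

gapForward <- function(L, x, train) {
  d <- dim(x)
  hw <- d[2L] * d[3L]
  tmp <- aperm(array(x, c(d[1L], hw, d[4L])), c(2L, 1L, 3L))
  if (train) L$cache <- d
  matrix(colSums(matrix(tmp, hw)), d[1L], d[4L]) / hw
}

gapBackward <- function(L, dout) {
  d <- L$cache
  L$cache <- NULL
  hw <- d[2L] * d[3L]
  tmp <- array(0, c(hw, d[1L], d[4L]))
  tmp[] <- rep(as.vector(dout) / hw, each = hw)
  array(aperm(tmp, c(2L, 1L, 3L)), d)
}

denseForward <- function(L, x, train) {
  if (train) L$cache <- x
  L$W %*% x + L$b
}

denseBackward <- function(L, dout) {
  L$gW <- dout %*% t(L$cache)
  L$gb <- rowSums(dout)
  x <- L$cache
  L$cache <- NULL
  crossprod(L$W, dout)
}

l2Forward <- function(L, x, train) {
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) stop("zero-norm vector cannot be L2-normalised")
  z <- sweep(x, 2L, nrm, `/`)
  if (train) L$cache <- list(z = z, nrm = nrm)
  z
}

l2Backward <- function(L, dout) {
  cc <- L$cache
  L$cache <- NULL
  sweep(dout - sweep(cc$z, 2L, colSums(cc$z * dout), `*`), 2L, cc$nrm, `/`)
}

pixshufForward <- function(L, x, train) {
  d <- dim(x); r <- L$r
  C <- d[1L] %/% (r * r)
  # input channel (c-1)*r^2 + (dr-1)*r + dc -> output (c, r*(h-1)+dr, r*(w-1)+dc)
  a <- array(x, c(r, r, C, d[2L], d[3L], d[4L]))   # dc, dr? order below
  # dim 1 = fastest input channel index: treat as dc within row, dr next
  a <- aperm(a, c(3L, 2L, 4L, 1L, 5L, 6L))         # C, dr, H, dc, W, N
  if (train) L$cache <- d
  array(a, c(C, r * d[2L], r * d[3L], d[4L]))
}

pixshufBackward <- function(L, dout) {
  d <- L$cache
  L$cache <- NULL
  r <- L$r
  C <- d[1L] %/% (r * r)
  a <- array(dout, c(C, r, d[2L], r, d[3L], d[4L]))
  a <- aperm(a, c(4L, 2L, 1L, 3L, 5L, 6L))
  array(a, d)
}

resForward <- function(L, x, train) {
  y <- convForward(L$conv1, x, train)
  y <- bnForward(L$bn1, y, train)
  y <- actForward(L$act, y, train)
  y <- convForward(L$conv2, y, train)
  y <- bnForward(L$bn2, y, train)
  s <- if (is.null(L$proj)) x else {
    bnForward(L$proj$bn, convForward(L$proj$conv, x, train), train)
  }
  pre <- y + s
  if (train) L$cachePre <- pre
  pmax(pre, 0)
}

resBackward <- function(L, dout) {
  dpre <- dout * (L$cachePre > 0)
  L$cachePre <- NULL
  dy <- bnBackward(L$bn2, dpre)
  dy <- convBackward(L$conv2, dy)
  dy <- actBackward(L$act, dy)
  dy <- bnBackward(L$bn1, dy)
  dx <- convBackward(L$conv1, dy)
  ds <- if (is.null(L$proj)) dpre else {
    convBackward(L$proj$conv, bnBackward(L$proj$bn, dpre))
  }
  dx + ds
}

layerForward <- function(L, x, train = FALSE) {
  switch(L$type,
    conv = convForward(L, x, train),
    bn = bnForward(L, x, train),
    act = actForward(L, x, train),
    gap = gapForward(L, x, train),
    dense = denseForward(L, x, train),
    l2norm = l2Forward(L, x, train),
    pixshuf = pixshufForward(L, x, train),
    resblock = resForward(L, x, train),
    stop("unknown layer type ", L$type))
}

layerBackward <- function(L, dout) {
  switch(L$type,
    conv = convBackward(L, dout),
    bn = bnBackward(L, dout),
    act = actBackward(L, dout),
    gap = gapBackward(L, dout),
    dense = denseBackward(L, dout),
    l2norm = l2Backward(L, dout),
    pixshuf = pixshufBackward(L, dout),
    resblock = resBackward(L, dout),
    stop("unknown layer type ", L$type))
}

netForward <- function(net, x, train = FALSE) {
  for (L in net) x <- layerForward(L, x, train)
  x
}

netBackward <- function(net, dout) {
  for (L in rev(net)) dout <- layerBackward(L, dout)
  dout
}

# Enumerate every parameter-bearing layer environment (descending into
# residual blocks and their projections).
netParamLayers <- function(net) {
  out <- list()
  for (L in net) {
    if (L$type == "resblock") {
      out <- c(out, list(L$conv1, L$bn1, L$conv2, L$bn2))
      if (!is.null(L$proj)) out <- c(out, list(L$proj$conv, L$proj$bn))
    } else if (L$type %in% c("conv", "dense", "bn")) {
      out <- c(out, list(L))
    }
  }
  out
}

.paramFields <- list(
  conv = c(W = "gW", b = "gb"),
  dense = c(W = "gW", b = "gb"),
  bn = c(gamma = "ggamma", beta = "gbeta")
)

# One SGD-with-momentum step over every parameter of `nets` (a list of
# networks trained jointly); gradients must have been populated by
# netBackward. `lrScale` optionally scales the learning rate per network.
sgdStep <- function(nets, lr, momentum = 0.9, weightDecay = 0,
                    lrScale = rep(1, length(nets))) {
  for (i in seq_along(nets)) {
    for (L in netParamLayers(nets[[i]])) {
      pf <- .paramFields[[L$type]]
      for (pn in names(pf)) {
        g <- get(pf[[pn]], envir = L)
        if (weightDecay > 0 && pn %in% c("W")) {
          g <- g + weightDecay * get(pn, envir = L)
        }
        vn <- paste0("v_", pn)
        v <- if (exists(vn, envir = L)) get(vn, envir = L) else 0
        v <- momentum * v - lr * lrScale[i] * g
        assign(vn, v, envir = L)
        assign(pn, get(pn, envir = L) + v, envir = L)
      }
    }
  }
  invisible(NULL)
}

# Scale all gradients of `nets` so their joint L2 norm is at most maxNorm.
clipGradients <- function(nets, maxNorm) {
  total <- 0
  for (net in nets) {
    for (L in netParamLayers(net)) {
      pf <- .paramFields[[L$type]]
      for (gn in pf) total <- total + sum(get(gn, envir = L)^2)
    }
  }
  total <- sqrt(total)
  if (is.finite(total) && total > maxNorm) {
    sc <- maxNorm / total
    for (net in nets) {
      for (L in netParamLayers(net)) {
        pf <- .paramFields[[L$type]]
        for (gn in pf) assign(gn, get(gn, envir = L) * sc, envir = L)
      }
    }
  }
  invisible(total)
}

# Cosine learning-rate schedule from lr0 down to lr0*floor.
cosineLr <- function(lr0, epoch, nEpochs, floorFrac = 0.01) {
  lr0 * (floorFrac + (1 - floorFrac) *
           0.5 * (1 + cos(pi * (epoch - 1) / max(1, nEpochs - 1))))
}

netWeights <- function(net) {
  lapply(netParamLayers(net), function(L) {
    pf <- .paramFields[[L$type]]
    stats::setNames(lapply(names(pf), get, envir = L), names(pf))
  })
}

# MD5 digest of all weights: a cheap identity check for determinism tests.
netDigest <- function(...) {
  w <- lapply(list(...), netWeights)
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(w, f, version = 2L)
  unname(tools::md5sum(f))
}

# Deep copy of a network (layers are environments, so assignment aliases).
netClone <- function(net) {
  cloneEnv <- function(e) {
    e2 <- new.env(parent = emptyenv())
    for (nm in ls(e, all.names = TRUE)) {
      v <- get(nm, envir = e)
      assign(nm, if (is.environment(v)) cloneEnv(v) else if (is.list(v) &&
               any(vapply(v, is.environment, TRUE))) {
        lapply(v, function(x) if (is.environment(x)) cloneEnv(x) else x)
      } else v, envir = e2)
    }
    e2
  }
  lapply(net, cloneEnv)
}

# ---- backbone / head builders ---------------------------------------------

# Small residual backbone for CPU-scale work: stem conv + 4 residual blocks
# (two stride-2), global average pooling, then a dense lift to the
# 512-dimensional feature h.
buildBackboneSmall <- function(width = 16L, hDim = 512L) {
  c(list(nnConv(1L, width, 3L), nnBN(width), nnAct("relu"),
         nnResBlock(width, 2L * width, 2L),
         nnResBlock(2L * width, 2L * width, 1L),
         nnResBlock(2L * width, 4L * width, 2L),
         nnResBlock(4L * width, 4L * width, 1L),
         nnGAP(), nnDense(4L * width, hDim)))
}

# 18-layer residual backbone (stem + 8 two-convolution blocks) adapted to
# single-channel input; the stem uses a 3x3 convolution, appropriate for
# particle-sized inputs.
buildBackboneResNet18 <- function() {
  c(list(nnConv(1L, 64L, 3L), nnBN(64L), nnAct("relu"),
         nnResBlock(64L, 64L, 1L), nnResBlock(64L, 64L, 1L),
         nnResBlock(64L, 128L, 2L), nnResBlock(128L, 128L, 1L),
         nnResBlock(128L, 256L, 2L), nnResBlock(256L, 256L, 1L),
         nnResBlock(256L, 512L, 2L), nnResBlock(512L, 512L, 1L),
         nnGAP()))
}

buildBackbone <- function(kind = c("small", "resnet18"), width = 16L,
                          hDim = 512L) {
  kind <- match.arg(kind)
  if (kind == "small") buildBackboneSmall(width, hDim)
  else buildBackboneResNet18()
}

# Two-layer perceptron projection head h (512) -> z (128), L2-normalised.
buildProjectionHead <- function(hDim = 512L, zDim = 128L) {
  list(nnDense(hDim, hDim), nnAct("relu"), nnDense(hDim, zDim), nnL2Norm())
}
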