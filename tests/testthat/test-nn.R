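# The neural-network core: every layer's backward pass is checked against
# central finite differences, through composite networks.

numGradCheck <- function(net, xdim, tol = 1e-5) {
  set.seed(42)
  x <- array(rnorm(prod(xdim)), xdim)
  out0 <- cryoclass:::netForward(net, x, train = TRUE)
  R <- array(rnorm(length(out0)),
             if (is.null(dim(out0))) length(out0) else dim(out0))
  loss <- function(xx) {
    sum(cryoclass:::netForward(net, xx, train = TRUE) * R)
  }
  dx <- cryoclass:::netBackward(net, R)
  eps <- 1e-5
  idx <- sample(length(x), min(40L, length(x)))
  for (i in idx) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g <- (loss(x1) - loss(x2)) / (2 * eps)
    expect_lt(abs(dx[i] - g) / max(1, abs(g)), tol)
  }
  # parameter gradients of the first parameter layer
  pls <- cryoclass:::netParamLayers(net)
  if (length(pls)) {
    L <- pls[[1L]]
    pf <- cryoclass:::.paramFields[[L$type]]
    pn <- names(pf)[1L]
    W0 <- get(pn, envir = L)
    cryoclass:::netForward(net, x, train = TRUE)
    cryoclass:::netBackward(net, R)
    ganal <- get(pf[[1L]], envir = L)
    for (i in sample(length(W0), min(10L, length(W0)))) {
      W1 <- W0; W1[i] <- W1[i] + eps
      assign(pn, W1, envir = L)
      up <- loss(x)
      W2 <- W0; W2[i] <- W2[i] - eps
      assign(pn, W2, envir = L)
      dn <- loss(x)
      assign(pn, W0, envir = L)
      g <- (up - dn) / (2 * eps)
      expect_lt(abs(ganal[i] - g) / max(1, abs(g)), tol)
    }
  }
  invisible(NULL)
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  numGradCheck(list(cryoclass:::nnConv(2L, 3L, 3L, stride = 2L)),
               c(2, 6, 6, 2))
  numGradCheck(list(cryoclass:::nnConv(1L, 2L, 3L)), c(1, 5, 5, 2))
})

test_that("normalisation, activation and pooling gradients check out", {
  set.seed(2)
  numGradCheck(list(cryoclass:::nnBN(3L)), c(3, 4, 4, 2))
  numGradCheck(list(cryoclass:::nnAct("lrelu")), c(2, 3, 3, 2))
  numGradCheck(list(cryoclass:::nnGAP()), c(3, 4, 4, 2))
  numGradCheck(list(cryoclass:::nnDense(5L, 4L), cryoclass:::nnL2Norm()),
               c(5, 3))
})

test_that("residual block, pixel shuffle and a full mini-net backprop correctly", {
  set.seed(3)
  numGradCheck(list(cryoclass:::nnResBlock(2L, 4L, 2L)), c(2, 6, 6, 2))
  numGradCheck(list(cryoclass:::nnPixelShuffle(2L)), c(8, 3, 3, 2))
  numGradCheck(list(cryoclass:::nnConv(1L, 4L, 3L), cryoclass:::nnBN(4L),
                    cryoclass:::nnAct("relu"),
                    cryoclass:::nnResBlock(4L, 8L, 2L),
                    cryoclass:::nnGAP(), cryoclass:::nnDense(8L, 6L)),
               c(1, 8, 8, 3))
})

test_that("pixel shuffle rearranges channels into space and inverts", {
  x <- array(seq_len(8 * 3 * 3 * 2), c(8, 3, 3, 2))
  L <- cryoclass:::nnPixelShuffle(2L)
  y <- cryoclass:::layerForward(L, x, train = TRUE)
  expect_identical(dim(y), c(2L, 6L, 6L, 2L))
  expect_identical(sort(as.vector(y)), sort(as.vector(x)))
  back <- cryoclass:::layerBackward(L, y)
  expect_identical(back, x)   # permutation round-trip
})

test_that("SGD with momentum reduces a simple quadratic loss deterministically", {
  run <- function() {
    net <- cryoclass:::withSeed(7L, function() {
      list(cryoclass:::nnDense(4L, 2L))
    })
    set.seed(8)
    x <- matrix(rnorm(4 * 32), 4, 32)
    Wtrue <- matrix(c(1, -2, 0.5, 3, -1, 2, 0, 1), 2, 4)
    y <- Wtrue %*% x
    losses <- numeric(50)
    for (i in 1:50) {
      out <- cryoclass:::netForward(net, x, train = TRUE)
      losses[i] <- mean((out - y)^2)
      cryoclass:::netBackward(net, 2 * (out - y) / length(out))
      cryoclass:::sgdStep(list(net), 0.05)
    }
    losses
  }
  l1 <- run()
  expect_lt(l1[50], 0.05 * l1[1])
  expect_identical(l1, run())   # bitwise determinism per seed
})
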