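# Contrastive pretext stage: augmentation, NT-Xent loss, feature
# extraction, neighbour mining, KNN validation.

test_that("augmented pairs are seeded, shaped and optional", {
  img <- fixProjection()
  p1 <- augmentPair(img, seed = 3L, size = 24L)
  p2 <- augmentPair(img, seed = 3L, size = 24L)
  expect_identical(p1, p2)
  expect_false(identical(p1$xi, p1$xj))
  expect_identical(dim(p1$xi), c(24L, 24L))
  p3 <- augmentPair(img, seed = 4L, size = 40L)
  expect_identical(dim(p3$xj), c(40L, 40L))    # any output size
  off <- augmentPair(img, seed = 5L, size = 24L, enabled = FALSE)
  expect_identical(off$xi, off$xj)
  # views are normalised
  expect_lt(abs(mean(p1$xi)), 1e-8)
  expect_lt(abs(sd(as.vector(p1$xi)) - 1), 1e-8)
})

test_that("NT-Xent closed forms: no negatives, uniform similarities", {
  # B = 1: only the positive in the denominator -> exactly 0
  z <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(ntXentLoss(z, tau = 0.5), 0)
  # all four embeddings identical, B = 2: softmax uniform over 3 candidates
  z4 <- matrix(rep(c(1, 0), each = 1, times = 4), 4, 2, byrow = TRUE)
  z4 <- z4 / sqrt(rowSums(z4^2))
  expect_equal(ntXentLoss(z4, tau = 0.5), log(3), tolerance = 1e-12)
})

test_that("NT-Xent equals the loop-based brute force on random batches", {
  set.seed(6)
  for (B in c(2L, 4L, 8L)) {
    z <- matrix(rnorm(2 * B * 16), 2 * B, 16)
    z <- z / sqrt(rowSums(z^2))
    for (tau in c(0.2, 0.5, 1)) {
      expect_equal(ntXentLoss(z, tau), ntXentBrute(z, tau),
                   tolerance = 1e-6)
    }
  }
  expect_error(ntXentLoss(matrix(0, 2, 3)), "zero-norm")
})

test_that("NT-Xent decreases as the positive similarity grows", {
  base <- c(1, 0, 0)
  mk <- function(theta) {
    z <- rbind(c(1, 0, 0), c(cos(theta), sin(theta), 0),
               c(0, 0, 1), c(0, sin(theta), cos(theta)))
    z / sqrt(rowSums(z^2))
  }
  losses <- vapply(c(1.2, 0.8, 0.4, 0.1), function(th) {
    ntXentLoss(mk(th), 0.5)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("NT-Xent gradient matches finite differences", {
  set.seed(7)
  zc <- matrix(rnorm(8 * 6), 8, 6)   # d x 2B, columns are samples
  g <- cryoclass:::ntXentGrad(zc, 0.5)
  eps <- 1e-6
  for (i in sample(length(zc), 12L)) {
    z1 <- zc; z1[i] <- z1[i] + eps
    z2 <- zc; z2[i] <- z2[i] - eps
    num <- (cryoclass:::ntXentGrad(z1, 0.5)$loss -
              cryoclass:::ntXentGrad(z2, 0.5)$loss) / (2 * eps)
    expect_lt(abs(g$dz[i] - num), 1e-5)
  }
})

test_that("feature extraction is deterministic, unit-norm, 512/128-dim", {
  stk <- randomStack(24L, 6L, seed = 4L)
  enc <- trainPretext(stk, pretextConfig("desk", epochs = 2L, batch = 6L,
                                         seed = 3L))
  emb <- extractFeatures(stk, enc)
  expect_identical(dim(features(emb)), c(6L, 512L))
  expect_identical(dim(projectedFeatures(emb)), c(6L, 128L))
  expect_true(all(abs(sqrt(rowSums(projectedFeatures(emb)^2)) - 1) < 1e-5))
  emb2 <- extractFeatures(stk, enc)
  expect_identical(features(emb), features(emb2))
  # duplicate image -> identical feature rows
  dup <- ParticleStack(array(rep(stk@images[, , 1L], 2), c(24, 24, 2)))
  ed <- extractFeatures(dup, enc)
  expect_equal(features(ed)[1L, ], features(ed)[2L, ], tolerance = 1e-12)
})

test_that("pretext training is seeded and its loss declines on toy classes", {
  ds <- buildDataset(datasetConfig(n = 64L, nPhantoms = 3L, classes = 1L,
                                   perClass = 8L, snr = 2, seed = 4L,
                                   kBlobs = 6L))
  proc <- preprocessStack(ds$stack)
  cfg <- pretextConfig("desk", epochs = 8L, batch = 24L, width = 8L,
                       seed = 9L)
  enc <- trainPretext(proc, cfg)
  lc <- lossCurve(enc)
  expect_length(lc, 8L)
  expect_true(all(is.finite(lc)))
  expect_lt(mean(tail(lc, 3L)), mean(head(lc, 3L)))   # overall decline
  enc2 <- trainPretext(proc, cfg)
  expect_identical(lossCurve(enc2), lc)
  expect_identical(cryoclass:::netDigest(enc@backbone),
                   cryoclass:::netDigest(enc2@backbone))
})

test_that("neighbour mining equals exhaustive search and excludes self", {
  set.seed(8)
  # three well-separated clusters of 5 points
  ctr <- diag(3) * 10
  z <- do.call(rbind, lapply(1:3, function(c) {
    matrix(rnorm(5 * 3, sd = 0.1), 5, 3) +
      matrix(ctr[c, ], 5, 3, byrow = TRUE)
  }))
  nb <- mineNeighbors(z, K = 4L)
  labs <- rep(1:3, each = 5)
  expect_true(all(matrix(labs[nb], nrow = 15) == labs)) # intra-cluster
  expect_true(all(nb != row(nb)))
  # brute-force agreement on random data
  x <- matrix(rnorm(20 * 6), 20, 6)
  nb2 <- mineNeighbors(x, K = 3L)
  xn <- x / sqrt(rowSums(x^2))
  S <- xn %*% t(xn); diag(S) <- -Inf
  for (i in 1:20) {
    expect_identical(nb2[i, ], order(-S[i, ], seq_len(20))[1:3])
  }
  # K = 1 on two identical points: each is the other's neighbour
  two <- rbind(c(1, 0), c(1, 0))
  expect_identical(as.vector(mineNeighbors(two, 1L)), c(2L, 1L))
  expect_error(mineNeighbors(x, 20L), "smaller")
})

test_that("KNN validation: separation, nesting, chance level", {
  set.seed(9)
  ctr <- diag(3) * 10
  z <- do.call(rbind, lapply(1:3, function(c) {
    matrix(rnorm(8 * 3, sd = 0.1), 8, 3) +
      matrix(ctr[c, ], 8, 3, byrow = TRUE)
  }))
  labs <- rep(1:3, each = 8)
  expect_equal(knnValidate(z, labs, K = 4L), 1)
  # top-5 >= top-1 always (random features, many classes)
  x <- matrix(rnorm(120 * 8), 120, 8)
  rl <- sample(1:11, 120, replace = TRUE)
  t1 <- knnValidate(x, rl, K = 5L, topM = 1L)
  t5 <- knnValidate(x, rl, K = 5L, topM = 5L)
  expect_gte(t5, t1)
  # chance level ~ 1/C for random balanced features
  big <- matrix(rnorm(1100 * 8), 1100, 8)
  bl <- rep(0:10, each = 100)
  acc <- knnValidate(big, bl, K = 5L)
  expect_lt(abs(acc - 1 / 11), 4 * sqrt((1 / 11) * (10 / 11) / 1100))
})
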