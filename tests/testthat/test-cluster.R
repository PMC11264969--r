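# Clustering stage: consistency loss, training, self-labelling, assignment.

test_that("neighbour-consistency loss closed forms", {
  oneHot <- c(1, rep(0, 10))
  expect_equal(scanLoss(oneHot, list(oneHot), oneHot, lambda = 0), 0)
  u <- rep(1 / 11, 11)
  expect_equal(scanLoss(u, list(u, u), u, lambda = 0), log(11),
               tolerance = 1e-12)
  # entropy term: uniform cluster mean maximises it, so larger lambda
  # strictly lowers the loss
  l1 <- scanLoss(u, list(u), u, lambda = 1)
  l5 <- scanLoss(u, list(u), u, lambda = 5)
  expect_lt(l5, l1)
  expect_error(scanLoss(u, list(u), u, lambda = -1), "lambda")
  expect_warning(scanLoss(oneHot, list(rev(oneHot)), u, 0), "clamped")
})

test_that("consistency loss equals the loop-based brute force", {
  set.seed(10)
  for (r in 1:20) {
    C <- sample(2:11, 1)
    nn <- sample(1:4, 1)
    rp <- function() { v <- runif(C); v / sum(v) }
    pa <- rp()
    pns <- replicate(nn, rp(), simplify = FALSE)
    cm <- rp()
    lam <- runif(1, 0, 6)
    expect_equal(scanLoss(pa, pns, cm, lam),
                 scanLossBrute(pa, pns, cm, lam), tolerance = 1e-6)
  }
})

test_that("batch loss gradient matches finite differences", {
  set.seed(11)
  C <- 5L; B <- 4L
  lA <- matrix(rnorm(C * B), C, B)
  lN <- matrix(rnorm(C * B), C, B)
  g <- cryoclass:::scanGrad(lA, lN, lambda = 3)
  eps <- 1e-6
  for (i in sample(length(lA), 8L)) {
    l1 <- lA; l1[i] <- l1[i] + eps
    l2 <- lA; l2[i] <- l2[i] - eps
    num <- (cryoclass:::scanGrad(l1, lN, 3)$loss -
              cryoclass:::scanGrad(l2, lN, 3)$loss) / (2 * eps)
    expect_lt(abs(g$dLogitA[i] - num), 1e-5)
  }
  for (i in sample(length(lN), 4L)) {
    l1 <- lN; l1[i] <- l1[i] + eps
    l2 <- lN; l2[i] <- l2[i] - eps
    num <- (cryoclass:::scanGrad(lA, l1, 3)$loss -
              cryoclass:::scanGrad(lA, l2, 3)$loss) / (2 * eps)
    expect_lt(abs(g$dLogitN[i] - num), 1e-5)
  }
})

test_that("cluster training declines, is seeded, and assigns simplex rows", {
  tc <- tinyCluster()
  lc <- lossCurve(tc$cm)
  expect_true(all(is.finite(lc)))
  expect_lt(mean(tail(lc, 3L)), mean(head(lc, 3L)))
  asg <- assignClusters(tc$cm, tc$proc)
  pCols <- grep("^p\\.", names(asg))
  expect_length(pCols, 3L)
  expect_true(all(abs(rowSums(asg[, pCols]) - 1) < 1e-5))
  expect_true(all(asg$label %in% 0:2))
  # determinism of the whole stage
  cm2 <- trainCluster(tc$enc, tc$proc, neighborTable(tc$emb), tc$ccfg)
  asg2 <- assignClusters(cm2, tc$proc)
  expect_identical(asg$label, asg2$label)
  # duplicate images get identical assignments
  n <- imageSide(tc$proc)
  dup <- ParticleStack(array(rep(getImage(tc$proc, 1L), 2), c(n, n, 2)))
  ad <- assignClusters(tc$cm, dup)
  expect_equal(unlist(ad[1L, pCols]), unlist(ad[2L, pCols]),
               tolerance = 1e-12)
  expect_error(trainCluster(tc$enc, tc$proc[1:2], neighborTable(tc$emb)[1:2, ],
                            clusterConfig("desk", nClasses = 3L)),
               "more samples")
})

test_that("neighbour consistency: most top neighbours agree after training", {
  tc <- tinyCluster()
  asg <- assignClusters(tc$cm, tc$proc)
  top <- neighborTable(tc$emb)[, 1L]
  expect_gte(mean(asg$label == asg$label[top]), 0.9)
})

test_that("self-labelling respects the threshold boundary and confidence", {
  tc <- tinyCluster()
  expect_message(out <- selfLabel(tc$cm, tc$proc, threshold = 1),
                 "unchanged")
  expect_identical(cryoclass:::netDigest(out@backbone, out@headLayer),
                   cryoclass:::netDigest(tc$cm@backbone, tc$cm@headLayer))
  expect_error(selfLabel(tc$cm, tc$proc, threshold = 1.2), "threshold")
  expect_error(selfLabel(tc$cm, tc$proc, threshold = 0), "threshold")
  sl <- selfLabel(tc$cm, tc$proc, threshold = 0.95, cfg = tc$ccfg)
  asg <- assignClusters(sl, tc$proc, threshold = 0.95)
  expect_true(all(asg$pseudo == (asg$prob > 0.95)))
  # confident subset at least as accurate as the whole set
  if (any(asg$pseudo) && !all(asg$pseudo)) {
    accAll <- clusteringAccuracy(asg$label, tc$labels)
    accConf <- clusteringAccuracy(asg$label[asg$pseudo],
                                  tc$labels[asg$pseudo])
    expect_gte(accConf, accAll - 1e-9)
  }
  # regression guard: self-labelling does not wreck accuracy
  accBefore <- clusteringAccuracy(assignClusters(tc$cm, tc$proc)$label,
                                  tc$labels)
  accAfter <- clusteringAccuracy(asg$label, tc$labels)
  expect_gte(accAfter, accBefore - 0.05)
})
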