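# Clustering metrics against brute-force oracles.

test_that("Hungarian-matched accuracy: worked examples and permutation
           invariance", {
  expect_equal(clusteringAccuracy(c(0, 0, 0, 1, 1, 2),
                                  c(0, 1, 0, 1, 2, 2)), 4 / 6)
  pred <- c(1, 1, 2, 2, 3, 3)
  expect_equal(clusteringAccuracy(pred, pred), 1)
  relab <- c(7, 7, 5, 5, 1, 1)
  expect_equal(clusteringAccuracy(relab, pred), 1)
  # constant prediction over k balanced classes -> 1/k
  expect_equal(clusteringAccuracy(rep(1, 12), rep(1:4, each = 3)), 1 / 4)
})

test_that("accuracy equals exhaustive permutation search on random cases", {
  for (r in 1:200) {
    n <- 5L + (r %% 20L)
    kp <- 2L + (r %% 5L)
    kt <- 2L + ((r * 7L) %% 5L)
    pred <- randomPartition(n, kp, seed = 1000L + r)
    truth <- randomPartition(n, kt, seed = 2000L + r)
    expect_equal(clusteringAccuracy(pred, truth),
                 accByPermutation(pred, truth))
  }
})

test_that("pair counts match the O(N^2) loop and the worked example", {
  pred <- c(1, 1, 2, 2, 2)       # {1,2}, {3,4,5}
  truth <- c(1, 1, 1, 2, 2)      # {1,2,3}, {4,5}
  expect_equal(pairCounts(pred, truth), c(tp = 2, fp = 2, fn = 2))
  expect_equal(fowlkesMallows(pred, truth), 0.5)
  expect_equal(pairCounts(1, 1), c(tp = 0, fp = 0, fn = 0))
  same <- c(1, 2, 1, 3)
  expect_equal(unname(pairCounts(same, same)[c("fp", "fn")]), c(0, 0))
  for (r in 1:200) {
    n <- 4L + (r %% 47L)
    pred <- randomPartition(n, 2L + (r %% 6L), seed = 3000L + r)
    truth <- randomPartition(n, 2L + ((r * 3L) %% 6L), seed = 4000L + r)
    expect_equal(unname(pairCounts(pred, truth)),
                 unname(pairCountsBrute(pred, truth)))
    expect_equal(fowlkesMallows(pred, truth), {
      pc <- pairCountsBrute(pred, truth)
      den <- sqrt((pc[1] + pc[2]) * (pc[1] + pc[3]))
      if (den == 0) 0 else unname(pc[1] / den)
    })
  }
})

test_that("FMI boundary cases", {
  x <- c(1, 1, 2, 2)
  expect_equal(fowlkesMallows(x, x), 1)
  expect_equal(fowlkesMallows(1:4, x), 0)       # singletons: TP = 0
})

test_that("NMI: identity, zero-entropy convention, chance level", {
  x <- rep(1:3, each = 5)
  expect_equal(nmiScore(x, x), 1)
  expect_equal(nmiScore(sample(x), rep(1, 15)), 0)
  set.seed(17)
  a <- sample(1:3, 1e4, replace = TRUE)
  b <- sample(1:3, 1e4, replace = TRUE)
  expect_lt(nmiScore(a, b), 0.05)
})

test_that("metrics are relabel-invariant and 1 iff partitions coincide", {
  for (r in 1:25) {
    n <- 10L + r
    pred <- randomPartition(n, 3L, seed = 5000L + r)
    truth <- randomPartition(n, 4L, seed = 6000L + r)
    relab <- c(9, 4, 7)[pred]
    expect_equal(clusteringAccuracy(relab, truth),
                 clusteringAccuracy(pred, truth))
    expect_equal(fowlkesMallows(relab, truth),
                 fowlkesMallows(pred, truth))
    expect_equal(nmiScore(relab, truth), nmiScore(pred, truth))
    same <- identical(unname(pairCounts(pred, truth)[c("fp", "fn")]),
                      c(0, 0))
    allOne <- isTRUE(all.equal(clusteringAccuracy(pred, truth), 1)) &&
      isTRUE(all.equal(fowlkesMallows(pred, truth), 1))
    expect_identical(allOne, same)
  }
})

test_that("the report joins by id, carries all fields, and works blind", {
  asg <- data.frame(id = sprintf("%02d", 1:9),
                    label = rep(0:2, each = 3),
                    prob = runif(9, 0.5, 1),
                    pseudo = rep(c(TRUE, FALSE, TRUE), 3))
  truth <- data.frame(id = sprintf("%02d", 1:9),
                      class = rep(c(2L, 0L, 1L), each = 3))
  rep1 <- clusteringReport(asg, truth)
  expect_equal(rep1$acc, 1)
  expect_equal(rep1$fmi, 1)
  expect_equal(rep1$nmi, 1)
  expect_true(all(c("tp", "fp", "fn", "confusion", "matching") %in%
                    names(rep1)))
  expect_equal(rep1$acc, clusteringAccuracy(asg$label, truth$class))
  blind <- clusteringReport(asg)
  expect_false("acc" %in% names(blind))
  expect_true(all(c("clusterSizes", "meanProb") %in% names(blind)))
  bad <- truth; bad$id <- paste0("x", bad$id)
  expect_error(clusteringReport(asg, bad), "disjoint")
  f <- withr::local_tempfile(fileext = ".json")
  clusteringReport(asg, truth, path = f)
  back <- jsonlite::read_json(f)
  expect_equal(back$acc, 1)
})
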