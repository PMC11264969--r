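# Simulator: phantoms, angle grid, projection, noise, dataset assembly.

test_that("phantoms are deterministic per seed and pass the asymmetry check", {
  ph <- fixPhantom()
  ph2 <- makePhantom(5L, n = 64L, kBlobs = 6L)
  expect_identical(ph$density, ph2$density)
  expect_true(all(ph$density >= 0))
  expect_gt(sum(ph$density), 0)
  p0 <- apply(ph$density, c(1, 2), sum)
  best <- max(vapply(seq(20, 340, 20), function(th) {
    cor(as.vector(p0), as.vector(rotateImage(p0, th, fill = 0)))
  }, numeric(1)))
  expect_lt(best, 0.95)
  expect_error(makePhantom(1L, n = 64L, kBlobs = 0L), "kBlobs")
  expect_error(makePhantom(1L, n = 31L), "even")
})

test_that("angle grid counts: rot half-open, tilt closed", {
  expect_identical(nrow(angleGrid(0, 360, 5, 90, 90, 5)), 72L)
  g <- angleGrid(0, 360, 360, 0, 0, 5)
  expect_identical(nrow(g), 1L)
  expect_identical(g$rot, 0)
  tg <- angleGrid(0, 5, 5, 0, 180, 5)
  expect_identical(range(tg$tilt), c(0, 180))   # endpoints included
  expect_identical(nrow(tg), 37L)
  expect_error(angleGrid(0, 360, 0), "positive")
  expect_error(angleGrid(10, 10, 5), "exceed")
})

test_that("projection: exact top view, mass conservation, linearity", {
  ph <- fixPhantom()
  expect_identical(projectVolume(ph, 0, 0), apply(ph$density, c(1, 2), sum))
  zero <- ph; zero$density[] <- 0
  expect_true(all(projectVolume(zero, 33, 57) == 0))
  tot <- sum(ph$density)
  set.seed(4)
  for (k in 1:20) {
    p <- projectVolume(ph, runif(1, 0, 360), runif(1, 0, 180))
    expect_lt(abs(sum(p) - tot) / tot, 0.01)
  }
  # linearity in the volume
  ph2 <- makePhantom(9L, n = 64L, kBlobs = 6L)
  mix <- ph; mix$density <- 2 * ph$density + 0.5 * ph2$density
  pm <- projectVolume(mix, 70, 40)
  expect_equal(pm, 2 * projectVolume(ph, 70, 40) +
                 0.5 * projectVolume(ph2, 70, 40), tolerance = 1e-10)
})

test_that("rotating the volume about the viewing axis rotates the projection", {
  # at tilt = 0 the rot angle is exactly an in-plane rotation of the top
  # view, which pins the simulator's angle convention to rotateImage's
  ph <- fixPhantom()
  top <- projectVolume(ph, 0, 0)
  msk <- discMask(64L, 0.8)
  for (psi in c(30, 90, 145)) {
    a <- projectVolume(ph, psi, 0)
    b <- rotateImage(top, psi, fill = 0)
    expect_lt(sqrt(mean((a - b)[msk]^2)) / sd(top[msk]), 0.02)
  }
})

test_that("injected noise hits the requested SNR and is seeded", {
  img <- fixProjection()
  expect_identical(addNoise(img, Inf, 1L), img)
  n1 <- addNoise(img, 0.5, 7L)
  expect_identical(n1, addNoise(img, 0.5, 7L))
  expect_false(identical(n1, addNoise(img, 0.5, 8L)))
  # var(noise) = var(signal)/snr within 1%, measured over ~1e5 pixels
  set.seed(1)
  bigs <- matrix(rnorm(320 * 320, sd = 2), 320, 320)   # var 4 signal
  noisy <- addNoise(bigs, 0.5, 3L)
  target <- var(as.vector(bigs)) / 0.5    # the definition, on measured var
  expect_lt(abs(var(as.vector(noisy - bigs)) / target - 1), 0.01)
  expect_error(addNoise(img, -1, 1L), "positive")
  expect_error(addNoise(img, 0, 1L), "positive")
})

test_that("empirical SNR of emitted images matches the request within 5%", {
  ds <- buildDataset(datasetConfig(n = 64L, classes = 2L, perClass = 3L,
                                   snr = 0.6, seed = 3L, kBlobs = 6L))
  cleanCfg <- datasetConfig(n = 64L, classes = 2L, perClass = 3L,
                            snr = Inf, seed = 3L, kBlobs = 6L)
  clean <- buildDataset(cleanCfg, phantoms = ds$phantoms)
  snrs <- vapply(seq_len(nImages(ds$stack)), function(k) {
    s <- clean$stack@images[, , k]
    n <- ds$stack@images[, , k] - s
    var(as.vector(s)) / var(as.vector(n))
  }, numeric(1))
  expect_true(all(abs(snrs / 0.6 - 1) < 0.05))
})

test_that("noise bank patches are seeded, structured and usable", {
  bank <- makeNoiseBank(64L, 5L, seed = 2L)
  expect_identical(nImages(bank), 5L)
  expect_identical(bank@images, makeNoiseBank(64L, 5L, seed = 2L)@images)
  img <- fixProjection()
  nb <- addNoise(img, 0.5, 4L, noiseBank = bank)
  expect_identical(nb, addNoise(img, 0.5, 4L, noiseBank = bank))
  expect_lt(abs(var(as.vector(nb - img)) /
                  (var(as.vector(img)) / 0.5) - 1), 0.15)
})

test_that("dataset builder emits the configured counts with full labels", {
  cfg <- datasetConfig(n = 64L, classes = 3L, perClass = 20L, seed = 2L,
                       kBlobs = 6L)
  ds <- buildDataset(cfg)
  expect_identical(nImages(ds$stack), 60L)
  expect_identical(nrow(ds$metadata), 60L)
  cnt <- table(ds$metadata$class)
  expect_true(all(cnt == 20L))                    # per-class exact
  expect_setequal(names(ds$metadata)[1:8],
                  c("id", "class", "rot", "tilt", "psi", "dx", "dy", "snr"))
  expect_true(all(ds$metadata$split %in% c("train", "val", "test")))
  expect_identical(particleIds(ds$stack), ds$metadata$id)
  expect_error(buildDataset(datasetConfig(classes = 0L)), "must be")
})
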