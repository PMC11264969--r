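# Adversarial denoiser: architecture contracts and training-progress
# properties (quality gates on synthetic pairs, never visual claims).

makePairs <- function(count = 20L, n = 32L, snr = 0.5, seed = 21L) {
  ph <- fixPhantom()
  set.seed(seed)
  clean <- lapply(seq_len(count), function(i) {
    img <- rotateImage(fixProjection(), runif(1, 0, 360), fill = 0)
    img[seq_len(n), seq_len(n)] <- img[16 + seq_len(n), 16 + seq_len(n)]
    img[seq_len(n), seq_len(n)]
  })
  noisy <- lapply(seq_along(clean), function(i) {
    addNoise(clean[[i]], snr, 500L + i)
  })
  list(noisy = ParticleStack(noisy), clean = ParticleStack(clean))
}

test_that("generator is shape-preserving and inference is deterministic", {
  pr <- makePairs(4L)
  den <- trainDenoiser(pr$noisy, pr$clean, epochs = 1L, batch = 4L,
                       width = 8L, nRes = 2L, seed = 2L)
  out <- denoiseStack(pr$noisy, den)
  expect_identical(dim(out@images), dim(pr$noisy@images))
  expect_true(all(is.finite(out@images)))
  out2 <- denoiseStack(pr$noisy, den)
  expect_identical(out@images, out2@images)
  # applying twice stays finite (stability smoke test)
  expect_true(all(is.finite(denoiseStack(out, den)@images)))
  expect_error(trainDenoiser(pr$noisy, pr$clean[1:2]), "pair up")
})

test_that("training reduces the reconstruction loss and is seeded", {
  pr <- makePairs(24L)
  den <- trainDenoiser(pr$noisy, pr$clean, epochs = 12L, batch = 8L,
                       width = 8L, nRes = 2L, seed = 3L)
  h <- den@history
  expect_identical(nrow(h), 12L)
  expect_lt(mean(tail(h$recon, 3L)), mean(head(h$recon, 3L)))
  den2 <- trainDenoiser(pr$noisy, pr$clean, epochs = 12L, batch = 8L,
                        width = 8L, nRes = 2L, seed = 3L)
  expect_identical(cryoclass:::netDigest(den@generator),
                   cryoclass:::netDigest(den2@generator))
  expect_false(identical(
    cryoclass:::netDigest(den@generator),
    cryoclass:::netDigest(trainDenoiser(pr$noisy, pr$clean, epochs = 12L,
                                        batch = 8L, width = 8L, nRes = 2L,
                                        seed = 4L)@generator)))
})

test_that("a trained denoiser improves held-out PSNR over the noisy input", {
  tr <- makePairs(30L, seed = 22L)
  te <- makePairs(12L, seed = 23L)
  den <- trainDenoiser(tr$noisy, tr$clean, epochs = 25L, batch = 10L,
                       width = 8L, nRes = 2L, lr = 0.02, seed = 5L)
  outs <- denoiseStack(te$noisy, den)
  gain <- vapply(seq_len(nImages(outs)), function(k) {
    clean <- te$clean@images[, , k]
    psnr(outs@images[, , k], clean) - psnr(te$noisy@images[, , k], clean)
  }, numeric(1))
  expect_gt(mean(gain), 0)
})

test_that("untrained models are refused", {
  pr <- makePairs(4L)
  den <- trainDenoiser(pr$noisy, pr$clean, epochs = 1L, batch = 4L,
                       width = 8L, nRes = 2L, seed = 2L)
  fake <- methods::new("DenoiserModel", generator = den@generator,
                       discriminator = den@discriminator,
                       history = den@history, trained = FALSE, seed = 1L)
  expect_error(denoiseStack(pr$noisy, fake), "untrained")
})
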