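# Frequency-domain alignment: polar spectra, rotation correlation, angle
# wrapping, parameter estimation, transforms, class alignment.

test_that("polar spectrum has (n/2) x 360 shape and symmetry properties", {
  img <- fixProjection()                     # n = 64
  pm <- polarSpectrum(img)
  expect_identical(dim(pm), c(32L, 360L))
  expect_true(all(pm >= 0))
  big <- matrix(0, 104, 104); big[40:60, 30:80] <- fixProjection()[1:21, 1:51]
  expect_identical(dim(polarSpectrum(big)), c(52L, 360L))
  expect_error(polarSpectrum(matrix(0, 64, 62)), "square")
  expect_error(polarSpectrum(matrix(0, 63, 63)), "even")
  # translation leaves the magnitude map unchanged
  tr <- translateImage(img, 5, 0, fill = 0)
  ptr <- polarSpectrum(tr)
  expect_lt(sqrt(mean((ptr - pm)^2)) / sqrt(mean(pm^2)), 2e-2)
  # rotation circularly shifts the angular axis: brute-force peak at +30
  p30 <- polarSpectrum(rotateImage(img, 30, fill = 0))
  sh <- vapply(0:359, function(s) {
    sum(pm * p30[, (((0:359) + s) %% 360) + 1])
  }, numeric(1))
  expect_lte(min(abs(c(which.max(sh) - 1, which.max(sh) - 1 - 180,
                       which.max(sh) - 1 - 360) - 30)), 1)
})

test_that("rotation correlation peaks at zero for identical maps and at the
           constructed offset for circular shifts", {
  pm <- polarSpectrum(fixProjection())
  auto <- rotationCorrelation(pm, pm)
  expect_equal(auto$angleOffset, 0, tolerance = 0.2)
  sh45 <- pm[, (((0:359) - 45) %% 360) + 1]   # exact 45-cell shift
  rc <- rotationCorrelation(sh45, pm)
  expect_equal(abs(rc$angleOffset), 45, tolerance = 0.2)
  expect_error(rotationCorrelation(pm, pm[1:10, ]), "shapes")
})

test_that("rotation correlation equals brute-force circular correlation", {
  set.seed(12)
  A <- matrix(runif(16 * 24), 16, 24)
  B <- matrix(runif(16 * 24), 16, 24)
  P <- rotationCorrelation(A, B, center = FALSE)$P
  brute <- matrix(0, 16, 24)
  for (dr in 0:15) {
    for (dc in 0:23) {
      s <- 0
      for (r in 1:16) {
        for (cc in 1:24) {
          s <- s + A[r, cc] * B[(r - 1 - dr) %% 16 + 1,
                                (cc - 1 - dc) %% 24 + 1]
        }
      }
      brute[dr + 1, dc + 1] <- s
    }
  }
  expect_equal(P, brute, tolerance = 1e-6)
})

test_that("independent noise maps do not produce a spuriously sharp peak", {
  set.seed(13)
  A <- matrix(runif(16 * 24), 16, 24)
  B <- matrix(runif(16 * 24), 16, 24)
  rc <- rotationCorrelation(A, B)
  expect_lt(rc$value, 3 * median(rc$P))
})

test_that("angle wrapping follows the printed piecewise map and is idempotent", {
  expect_identical(wrapAngle(0), 0)
  expect_equal(wrapAngle(3 * pi / 2), -pi / 2)
  expect_equal(wrapAngle(pi), pi)
  expect_equal(wrapAngle(pi / 3), pi / 3)
  expect_lt(abs(wrapAngle(2 * pi - 1e-9) - (-1e-9)), 1e-12)
  grid <- seq(0, 2 * pi, length.out = 720)
  w <- wrapAngle(grid)
  expect_true(all(w > -pi - 1e-12 & w <= pi + 1e-12))
  expect_equal(wrapAngle(w), w, tolerance = 1e-12)
  expect_error(wrapAngle(Inf), "finite")
})

test_that("rotation estimation recovers known angles with Friedel resolution", {
  ref <- fixProjection()
  expect_lt(abs(estimateRotation(ref, ref)$omegaDeg), 0.5)
  for (psi in c(30, 200)) {
    mov <- rotateImage(ref, psi, fill = 0)
    est <- estimateRotation(ref, mov)
    expect_true(est$ambiguityResolved)
    want <- ((psi + 180) %% 360) - 180
    err <- abs(((est$omegaDeg - want + 180) %% 360) - 180)
    expect_lt(err, 1)
  }
  flat <- matrix(1, 64, 64)
  expect_error(estimateRotation(flat, flat), "flat")
})

test_that("translation estimation is exact for integer and sub-pixel shifts", {
  ref <- fixProjection()
  same <- estimateTranslation(ref, ref)
  expect_equal(c(same$dx, same$dy), c(0, 0))
  mv <- translateImage(ref, 3, -2, fill = 0)
  tr <- estimateTranslation(ref, mv)
  # the integer stage is exact; the sub-pixel polish may move the estimate
  # by its 0.01-px granularity
  expect_equal(c(tr$dx, tr$dy), c(3, -2), tolerance = 0.02)
  mv2 <- translateImage(ref, 1.5, 0, fill = 0)
  tr2 <- estimateTranslation(ref, mv2)
  expect_lt(abs(tr2$dx - 1.5), 0.5)
  expect_lt(abs(tr2$dy), 0.5)
  expect_error(estimateTranslation(matrix(2, 8, 8), matrix(2, 8, 8)),
               "flat")
})

test_that("transformImage identity, inverse roundtrip, and full alignment", {
  img <- fixProjection()
  expect_identical(transformImage(img, list(omega = 0, dx = 0, dy = 0)),
                   img)
  # (dx, dy) live in the rotation-compensated frame, so building the
  # forward transform as rotate(translate(img)) makes (omega, dx, dy) its
  # exact inverse under transformImage's rotate-then-translate order
  fwd <- rotateImage(translateImage(img, 3, -2, fill = 0), 40, fill = 0)
  params <- list(omega = 40 * pi / 180, dx = 3, dy = -2)
  back <- transformImage(fwd, params)
  ctr <- discMask(64L, 0.7)
  expect_lt(sqrt(mean((back - img)[ctr]^2)) / sd(img[ctr]), 0.05)
})

test_that("class alignment collapses variance and honours exclusions", {
  ref <- fixProjection()
  set.seed(14)
  imgs <- lapply(1:6, function(i) {
    translateImage(rotateImage(ref, runif(1, 0, 360), fill = 0),
                   runif(1, -4, 4), runif(1, -4, 4), fill = 0)
  })
  stk <- ParticleStack(imgs)
  al <- alignClass(stk, refIdx = 1L)
  v0 <- mean(apply(stk@images, c(1, 2), var))
  v1 <- mean(apply(al$aligned@images, c(1, 2), var))
  expect_lt(v1, 0.1 * v0)
  expect_identical(nrow(al$params), 6L)
  # identical copies align to identity
  cp <- ParticleStack(lapply(1:3, function(i) ref))
  ai <- alignClass(cp, refIdx = 2L)
  expect_true(all(abs(ai$params$omegaDeg) < 0.5))
  expect_true(all(abs(c(ai$params$dx, ai$params$dy)) < 0.5))
  # exclusions remove exactly the named ids
  ids <- particleIds(stk)
  ax <- alignClass(stk, refIdx = 1L, exclude = ids[c(2, 5)])
  expect_identical(particleIds(ax$aligned), ids[-c(2, 5)])
  expect_identical(ax$excluded, ids[c(2, 5)])
  expect_error(alignClass(stk, refIdx = 1L, exclude = "nope"), "unknown")
  expect_error(alignClass(stk, refIdx = 1L, exclude = ids), "empty")
})
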