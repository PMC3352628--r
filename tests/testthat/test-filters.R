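test_that("convolve2D agrees with a brute-force nested-loop oracle", {
  set.seed(21)
  for (trial in 1:20) {
    im <- matrix(rnorm(64), 8, 8)
    K <- sample(c(3, 5), 1)
    k <- matrix(rnorm(K * K), K, K)
    for (border in c("reflect", "zero"))
      expect_lt(max(abs(convolve2D(im, k, border) -
                        bruteConvolve(im, k, border))), 1e-10)
  }
})

test_that("convolution identities hold", {
  set.seed(22)
  im <- matrix(rnorm(49), 7, 7)
  idk <- matrix(0, 3, 3); idk[2, 2] <- 1
  expect_equal(convolve2D(im, idk), im)
  ## impulse response reproduces the kernel (true convolution)
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  k <- matrix(rnorm(9), 3, 3)
  expect_equal(convolve2D(imp, k, "zero")[3:5, 3:5], k)
  ## box kernel on an impulse spreads 1/9 over the neighbourhood
  out <- convolve2D(imp, matrix(1 / 9, 3, 3), "zero")
  expect_equal(out[3:5, 3:5], matrix(1 / 9, 3, 3))
  expect_equal(sum(out), 1)
  ## zero-sum kernels annihilate constants under reflection
  zs <- k - mean(k)
  expect_lt(max(abs(convolve2D(matrix(5, 6, 6), zs, "reflect"))), 1e-12)
  expect_error(convolve2D(im, matrix(1, 2, 2)), class = "ctsim_invalidParameter")
  expect_error(convolve2D(matrix(1, 2, 2), matrix(1, 3, 3)),
               class = "ctsim_invalidParameter")
})

test_that("box smoothing reduces noise variance and degenerates to identity", {
  set.seed(23)
  im <- matrix(rnorm(128 * 128), 128, 128)
  expect_lt(var(as.vector(smoothImage(im, 3))), var(as.vector(im)))
  expect_lt(var(as.vector(smoothImage(im, 5))),
            var(as.vector(smoothImage(im, 3))))
  expect_identical(smoothImage(im, 1), im)
  expect_equal(smoothImage(matrix(7, 9, 9), 3), matrix(7, 9, 9))
  expect_error(smoothImage(im, 4), class = "ctsim_invalidParameter")
})

test_that("Sobel magnitude is zero on constants, 4h on a step, and rotates with the image", {
  expect_equal(sobelEdges(matrix(3, 5, 5)), matrix(0, 5, 5))
  h <- 37
  step <- cbind(matrix(0, 6, 3), matrix(h, 6, 3))
  mag <- sobelEdges(step)
  expect_equal(mag[3, 3], 4 * h)
  expect_equal(mag[3, 4], 4 * h)
  expect_equal(mag[3, 1], 0)
  set.seed(24)
  im <- matrix(rnorm(36), 6, 6)
  rot <- t(im)[, 6:1]                       # 90 degree rotation
  magRot <- sobelEdges(rot)
  expect_equal(magRot, t(sobelEdges(im))[, 6:1], tolerance = 1e-12)
  expect_error(sobelEdges(matrix(1, 2, 5)), class = "ctsim_invalidParameter")
})

test_that("thresholding follows the >= rule and is monotone and idempotent", {
  im <- matrix(c(-5, 70, 20, 71), 2, 2)    # [[ -5, 20], [70, 71]] row-wise
  mk <- thresholdMask(im, 20)
  expect_identical(voxelData(mk), matrix(c(0L, 1L, 1L, 1L), 2, 2))
  expect_identical(voxelData(thresholdMask(matrix(c(1, 19.9), 1, 2), 20)),
                   matrix(0L, 1, 2))
  ## pixel exactly at T is object
  expect_identical(voxelData(thresholdMask(matrix(20, 2, 2), 20)),
                   matrix(1L, 2, 2))
  ## monotone: raising T never adds object pixels
  set.seed(25)
  im2 <- matrix(runif(100, -100, 100), 10, 10)
  prev <- voxelData(thresholdMask(im2, -100))
  for (T in c(-50, 0, 50, 100)) {
    cur <- voxelData(thresholdMask(im2, T))
    expect_true(all(cur <= prev))
    prev <- cur
  }
  ## idempotent on its own output with T = 1
  out <- voxelData(thresholdMask(im2, 10))
  expect_identical(voxelData(thresholdMask(out + 0, 1)), out)
})

test_that("histogram threshold finds the valley between tissue modes, with midpoint fallback", {
  set.seed(26)
  img <- matrix(c(rnorm(6000, -800, 150), rnorm(6000, 40, 150)), 120, 100)
  T1 <- histogramThreshold(img, c(-600, 0))
  expect_gt(T1, -600); expect_lt(T1, 0)
  ## exhaustive scan of the smoothed histogram confirms the valley location:
  ## counts near the returned T are no larger than anywhere shallower
  valleyBand <- img[img > T1 - 40 & img < T1 + 40]
  loBand <- img[img > -600 & img < -520]
  expect_lt(length(valleyBand) / 80, length(loBand) / 80)
  expect_equal(histogramThreshold(matrix(5, 10, 10), c(0, 10)), 5)
  expect_error(histogramThreshold(img, c(10, 10)),
               class = "ctsim_invalidParameter")
})
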