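test_that("boundary tracking walks a 3x3 block's 8 border pixels and closes", {
  m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
  cc <- trackBoundary(binaryMask(m, c(1, 1)), c(3, 3))
  expect_true(isClosed(cc))
  pts <- contourPoints(cc)
  expect_identical(nrow(pts), 8L)
  px <- round(pts + 0.5)                    # back to pixel indices
  expect_setequal(paste(px[, 1], px[, 2]),
                  paste(rep(2:4, times = 3), rep(2:4, each = 3))[-5])
  ## consecutive traced pixels are 8-adjacent and the chain closes
  gaps <- abs(diff(rbind(px, px[1, ])))
  expect_true(all(gaps <= 1))
})

test_that("a single object pixel traces to a one-point closed contour", {
  m <- matrix(0L, 4, 4); m[2, 3] <- 1L
  cc <- trackBoundary(binaryMask(m, c(1, 1)), c(2, 3))
  expect_identical(nrow(contourPoints(cc)), 1L)
  expect_true(isClosed(cc))
  expect_error(trackBoundary(binaryMask(matrix(0L, 4, 4), c(1, 1)), c(2, 2)),
               class = "ctsim_noObject")
})

test_that("traced boundaries equal the morphological oracle on 100 random masks", {
  set.seed(31)
  done <- 0
  while (done < 100) {
    comp <- randomBlobMask(24)
    if (is.null(comp)) next
    oracle <- boundaryOracle(comp)
    st <- which(comp == 1, arr.ind = TRUE)[1, ]
    pts <- contourPoints(trackBoundary(binaryMask(comp, c(1, 1)), st))
    px <- round(pts + 0.5)
    traced <- (px[, 2] - 1) * 24 + px[, 1]
    expect_true(setequal(oracle, traced))
    done <- done + 1
  }
})

test_that("background seeds are relocated strictly inside the nearest region", {
  m <- matrix(0L, 20, 20); m[8:14, 8:14] <- 1L
  bm <- binaryMask(m, c(1, 1))
  ## already inside: unchanged
  expect_identical(relocateSeedOutside(bm, c(10L, 10L)), c(10L, 10L))
  ## background seed left of the block: lands inside with all-object 4-neighbourhood
  px <- relocateSeedOutside(bm, c(10, 2))
  expect_identical(m[px[1], px[2]], 1L)
  expect_true(all(m[px[1] + c(-1, 1), px[2]] == 1L))
  expect_true(all(m[px[1], px[2] + c(-1, 1)] == 1L))
  ## analytic disk: relocated seed is a disk member
  yg <- matrix(1:30, 30, 30); xg <- t(yg)
  disk <- matrix(as.integer((yg - 15)^2 + (xg - 20)^2 <= 36), 30, 30)
  p2 <- relocateSeedOutside(binaryMask(disk, c(1, 1)), c(15, 2))
  expect_true((p2[1] - 15)^2 + (p2[2] - 20)^2 <= 36)
  expect_error(relocateSeedOutside(binaryMask(matrix(0L, 5, 5), c(1, 1)),
                                   c(2, 2)),
               class = "ctsim_noObject")
})

test_that("small-region suppression removes areas at or below the threshold only", {
  m <- matrix(0L, 30, 30)
  m[2:3, 2:3] <- 1L                          # 4 px at 10x10 mm = 4 cm^2
  m[10:25, 10:25] <- 1L                      # 256 cm^2
  out <- voxelData(removeSmallRegions(binaryMask(m, c(10, 10)), 6))
  expect_identical(sum(out[2:3, 2:3]), 0L)
  expect_identical(sum(out), 256L)
  ## multiple small spots inside a large region's bounding area all vanish
  m2 <- matrix(0L, 40, 40)
  m2[5:35, 5:35] <- 1L
  m2[c(2, 38), c(2, 38)] <- 1L
  out2 <- voxelData(removeSmallRegions(binaryMask(m2, c(10, 10)), 6))
  expect_identical(sum(out2), sum(m2[5:35, 5:35]))
  ## empty result allowed
  expect_identical(sum(voxelData(removeSmallRegions(
    binaryMask(m * 0L, c(10, 10)), 6))), 0L)
})

test_that("region growing matches the flood-fill oracle over a delta grid", {
  set.seed(32)
  for (trial in 1:25) {
    v <- array(sample(0:4, 16^3 / 16, TRUE) * 40, c(8, 8, 8))
    vol <- voxelVolume(v, c(1, 1, 1))
    for (delta in c(0, 20, 40, 80)) {
      seed <- sample(1:8, 3, TRUE)
      got <- voxelData(regionGrow(vol, seed, delta)) == 1
      expect_identical(got, floodFillOracle(voxelData(vol), seed, delta),
                       info = sprintf("trial %d delta %g", trial, delta))
    }
  }
})

test_that("region growing respects homogeneous block boundaries", {
  a <- array(0, c(4, 4, 4)); a[, , 3:4] <- 500
  vol <- voxelVolume(a, c(1, 1, 1))
  expect_identical(sum(voxelData(regionGrow(vol, c(2, 2, 1), 50))), 32L)
  expect_identical(sum(voxelData(regionGrow(vol, c(2, 2, 3), 0))), 32L)
  ## uniform volume floods entirely for any positive delta
  u <- voxelVolume(array(100, c(3, 4, 5)), c(1, 1, 1))
  expect_identical(sum(voxelData(regionGrow(u, c(1, 1, 1), 1))), 60L)
  expect_error(regionGrow(vol, c(9, 1, 1), 10),
               class = "ctsim_invalidParameter")
})

test_that("structures are recovered from the thorax phantom with high overlap", {
  ph <- generateThorax(smallThoraxSpec())
  gt <- groundTruthMasks(ph$truth)
  ## the spine bar is lower here: at this coarse grid its radius is only
  ## ~2.5 pixels, so raster quantisation dominates the overlap
  cases <- list(left_lung = list(c(8L, 30L, 22L), c(-950, -300), 0.9),
                spine = list(c(8L, 44L, 32L), c(300, 1500), 0.75))
  for (nm in names(cases)) {
    sr <- segmentStructure(ph$volume, seedPoint(cases[[nm]][[1]]),
                           smallParams(cases[[nm]][[2]]), structure = nm)
    expect_gt(diceCoefficient(structureMask(sr), gt[[nm]]),
              cases[[nm]][[3]])
  }
})

test_that("a background seed outside the body finds the external (skin) outline first", {
  ph <- generateThorax(smallThoraxSpec())
  gt <- groundTruthMasks(ph$truth)
  sr <- segmentStructure(ph$volume, seedPoint(c(8L, 2L, 32L)),
                         smallParams(c(-900, 3071)), structure = "body")
  expect_gt(diceCoefficient(structureMask(sr), gt$body), 0.95)
})

test_that("a seed on a small spot is retargeted to the larger organ (inside-point rule)", {
  ph <- generateThorax(smallThoraxSpec())
  v <- voxelData(ph$volume)
  ## plant a small lung-valued pocket in soft tissue near the left lung:
  ## in-window, but area ~0.05 cm^2 < suppression threshold
  v[8, 14:15, 20:21] <- -800
  vol <- voxelVolume(v, spacing = spacing(ph$volume))
  sr <- segmentStructure(vol, seedPoint(c(8L, 14L, 20L)),
                         smallParams(c(-950, -300)), structure = "left_lung")
  m <- voxelData(structureMask(sr))
  expect_identical(m[8, 14, 20], 0L)       # the spot itself was ignored
  expect_gt(diceCoefficient(structureMask(sr),
                            groundTruthMasks(ph$truth)$left_lung), 0.9)
})

test_that("segmentation is deterministic and its contours rasterise back to its mask", {
  ph <- generateThorax(smallThoraxSpec())
  sd <- seedPoint(c(8L, 30L, 22L))
  pars <- smallParams(c(-950, -300))
  a <- segmentStructure(ph$volume, sd, pars)
  b <- segmentStructure(ph$volume, sd, pars)
  expect_identical(voxelData(structureMask(a)), voxelData(structureMask(b)))
  refilled <- contoursToMask(structureContours(a), ph$volume)
  expect_identical(voxelData(refilled), voxelData(structureMask(a)))
})

test_that("an absent structure at the seed slice is an error; vanishing mid-stack is a warning record", {
  ph <- generateThorax(smallThoraxSpec())
  expect_error(segmentStructure(ph$volume, seedPoint(c(1L, 30L, 22L)),
                                smallParams(c(-950, -300))),
               class = "ctsim_structureAbsent")
  sr <- segmentStructure(ph$volume, seedPoint(c(8L, 30L, 22L)),
                         smallParams(c(-950, -300)))
  expect_true(length(sr@warnings) >= 1)     # lungs end inside the stack
})
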