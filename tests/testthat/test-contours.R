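test_that("area and periphery match analytic values for squares, triangles and near-circles", {
  sq <- contour2D(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0)))
  expect_equal(contourArea(sq), 1)
  expect_equal(contourPeriphery(sq), 4)
  tri <- contour2D(cbind(c(0, 30, 0), c(0, 0, 40)))
  expect_equal(contourArea(tri), 6)
  gon <- regularPolygonContour(256, 10)
  expect_lt(abs(contourArea(gon) / pi - 1), 0.001)
  expect_lt(abs(contourPeriphery(gon) / (2 * pi) - 1), 0.001)
  ## open polyline: two points 25 mm apart
  seg <- contour2D(cbind(c(0, 0), c(0, 25)), closed = FALSE)
  expect_equal(contourPeriphery(seg), 2.5)
  expect_error(contourArea(seg), class = "ctsim_invalidParameter")
})

test_that("decimation retains exactly floor(N(1-k/100)) points as a subsequence", {
  makeC <- function(N) regularPolygonContour(N, 10)
  expect_identical(nrow(contourPoints(decimateContour(makeC(530), 20))), 424L)
  expect_identical(nrow(contourPoints(decimateContour(makeC(712), 20))), 569L)
  expect_identical(nrow(contourPoints(decimateContour(makeC(418), 20))), 334L)
  c10 <- makeC(10)
  d5 <- decimateContour(c10, 50)
  expect_identical(nrow(contourPoints(d5)), 5L)
  ## subsequence of the original, first point retained, order preserved
  orig <- apply(contourPoints(c10), 1, paste, collapse = ",")
  kept <- apply(contourPoints(d5), 1, paste, collapse = ",")
  expect_identical(kept[1], orig[1])
  expect_false(is.unsorted(match(kept, orig)))
  expect_identical(contourPoints(decimateContour(c10, 0)),
                   contourPoints(c10))
  expect_error(decimateContour(c10, 100), class = "ctsim_invalidParameter")
  expect_error(decimateContour(regularPolygonContour(4, 5), 80),
               class = "ctsim_invalidParameter")
})

test_that("20% decimation of a 512-point circle shifts area and periphery by under 2%", {
  gon <- regularPolygonContour(512, 10)
  dec <- decimateContour(gon, 20)
  expect_lt(abs(contourArea(dec) / contourArea(gon) - 1), 0.02)
  expect_lt(abs(contourPeriphery(dec) / contourPeriphery(gon) - 1), 0.02)
})

test_that("contour interpolation blends matched sectors linearly", {
  sq <- function(L) contour2D(cbind(c(-L, -L, L, L), c(-L, L, L, -L)))
  mid <- interpolateContours(sq(10), sq(20), 0.5, sectors = 64)
  expect_lt(abs(contourArea(mid) / 9 - 1), 0.01)   # side 30 mm -> 9 cm^2
  ## t -> 0 limit equals the resampled first contour
  m0 <- interpolateContours(sq(10), sq(10), 0.3, sectors = 32)
  expect_lt(max(abs(contourPoints(m0) -
                    contourPoints(interpolateContours(sq(10), sq(10), 0.9,
                                                      sectors = 32)))), 1e-9)
  ## circles: every sector radius is the mean of the two radii (sector count
  ## divides the vertex count so rays pass through exact vertices)
  c1 <- regularPolygonContour(256, 3)
  c2 <- regularPolygonContour(256, 7)
  midC <- interpolateContours(c1, c2, 0.5, sectors = 64)
  r <- sqrt(rowSums(contourPoints(midC)^2))
  expect_lt(max(abs(r - 5)), 1e-9)
  expect_error(interpolateContours(c1, c2, 1.5), class = "ctsim_invalidParameter")
  degen <- contour2D(cbind(c(0, 0, 0), c(0, 1, 2)))
  expect_error(interpolateContours(degen, c2, 0.5),
               class = "ctsim_degenerateContour")
})

test_that("interpolation is independent of the input winding direction", {
  c1 <- regularPolygonContour(64, 4)
  c2 <- regularPolygonContour(64, 9, center = c(1, -2))
  rev2 <- contour2D(contourPoints(c2)[64:1, ])
  a <- interpolateContours(c1, c2, 0.4, sectors = 32)
  b <- interpolateContours(c1, rev2, 0.4, sectors = 32)
  expect_lt(max(abs(contourPoints(a) - contourPoints(b))), 1e-9)
})

test_that("rasterisation counts pixel centres, matching the segmentation fill", {
  ## 10x10 px square traced on the grid -> 100 object pixels
  tmpl <- voxelVolume(array(0, c(1, 20, 20)), spacing = c(1, 1, 1))
  box <- matrix(0L, 20, 20); box[6:15, 6:15] <- 1L
  cc <- trackBoundary(binaryMask(box, c(1, 1)), c(10, 10))
  cc@slice <- 1L
  mk <- contoursToMask(contourSet(list(cc), sliceSpacing = 1), tmpl)
  expect_identical(sum(voxelData(mk)), 100L)
  ## empty set -> empty mask
  empty <- contoursToMask(contourSet(list(), sliceSpacing = 1), tmpl)
  expect_identical(sum(voxelData(empty)), 0L)
  ## out-of-bounds contour is refused
  far <- contour2D(cbind(c(0, 0, 50), c(0, 50, 50)), slice = 1L)
  expect_error(contoursToMask(contourSet(list(far), sliceSpacing = 1), tmpl),
               class = "ctsim_outOfBounds")
})

test_that("mask -> boundary -> mask round-trips reproduce random blobs", {
  set.seed(41)
  tmpl <- voxelVolume(array(0, c(1, 32, 32)), spacing = c(1, 1, 1))
  done <- 0
  while (done < 30) {
    comp <- randomBlobMask(32)
    if (is.null(comp) || sum(comp) < 6) next
    st <- which(comp == 1, arr.ind = TRUE)[1, ]
    cc <- trackBoundary(binaryMask(comp, c(1, 1)), st)
    cc@slice <- 1L
    filled <- contoursToMask(contourSet(list(cc), sliceSpacing = 1), tmpl)
    expect_gte(diceCoefficient(voxelData(filled)[1, , ], comp), 0.99)
    done <- done + 1
  }
})

test_that("contour sets survive the JSON and CSV exports", {
  td <- withr::local_tempdir()
  cs <- contourSet(list(
    contour2D(cbind(c(0, 0, 5, 5), c(0, 5, 5, 0)), slice = 2L),
    contour2D(cbind(c(1, 1, 4), c(1, 4, 4)), slice = 3L)),
    structure = "lung", sliceSpacing = 2.5)
  writeContoursJSON(cs, file.path(td, "c.json"))
  back <- readContoursJSON(file.path(td, "c.json"))[[1]]
  expect_identical(structureName(back), "lung")
  expect_equal(back@sliceSpacing, 2.5)
  expect_equal(contourPoints(back@contours[[1]]),
               contourPoints(cs@contours[[1]]), ignore_attr = TRUE)
  writeContoursCSV(cs, file.path(td, "c.csv"))
  df <- read.csv(file.path(td, "c.csv"))
  expect_identical(nrow(df), 7L)
  expect_identical(sort(unique(df$slice)), c(2L, 3L))
})
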