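## Shared slab fixture: constant-HU volume, parallel rays normal to it.
slabSetup <- function(nSlices = 20, hu = 500) {
  v <- voxelVolume(array(hu, c(nSlices, 4, 4)), spacing = c(1, 5, 5))
  cam <- camera("parallel", direction = c(1, 0, 0),
                center = c(nSlices / 2, 10, 10),
                imageSize = c(3L, 3L), pixelPitch = 2)
  list(v = v, cam = cam, D = nSlices)
}

test_that("a radiograph of a homogeneous slab follows Beer-Lambert", {
  s <- slabSetup(20)
  K <- 0.01
  tf <- transferFunction(hu = c(0, 500), attenuation = c(K, K))
  r <- renderDRR(s$v, s$cam, tf, step = s$D / 100)
  expect_lt(abs(renderImage(r)[2, 2] / exp(-K * s$D) - 1), 0.005)
  ## zero attenuation -> I0 everywhere
  tf0 <- transferFunction(hu = c(0, 500), attenuation = c(0, 0))
  expect_true(all(renderImage(renderDRR(s$v, s$cam, tf0, 1)) == 1))
  ## I0 scales linearly
  expect_equal(renderImage(renderDRR(s$v, s$cam, tf0, 1, I0 = 3))[1, 1], 3)
  ## transparent mode has no surface: depth buffer at far
  expect_true(all(zBuffer(r) == r@far))
})

test_that("doubling the slab thickness doubles the attenuation exponent", {
  K <- 0.01
  tf <- transferFunction(hu = c(0, 500), attenuation = c(K, K))
  r1 <- slabSetup(20); r2 <- slabSetup(40)
  i1 <- renderImage(renderDRR(r1$v, r1$cam, tf, 0.2))[2, 2]
  i2 <- renderImage(renderDRR(r2$v, r2$cam, tf, 0.2))[2, 2]
  expect_equal(log(i2) / log(i1), 2, tolerance = 1e-9)
})

test_that("halving the march step changes the slab radiograph by under 0.5%", {
  s <- slabSetup(20)
  tf <- transferFunction(hu = c(0, 500), attenuation = c(0.012, 0.012))
  a <- renderImage(renderDRR(s$v, s$cam, tf, 0.4))[2, 2]
  b <- renderImage(renderDRR(s$v, s$cam, tf, 0.2))[2, 2]
  expect_lt(abs(a / b - 1), 0.005)
})

test_that("adding attenuation never brightens a radiograph pixel", {
  set.seed(61)
  a <- array(sample(0:100, 8^3, TRUE), c(8, 8, 8))
  v1 <- voxelVolume(a, c(1, 1, 1))
  a2 <- a; a2[4, , ] <- a2[4, , ] + 300     # extra attenuating layer
  v2 <- voxelVolume(a2, c(1, 1, 1))
  cam <- camera("parallel", direction = c(1, 0, 0), center = c(4, 4, 4),
                imageSize = c(6L, 6L), pixelPitch = 1.2)
  tf <- transferFunction(hu = c(0, 400), attenuation = c(0, 0.02))
  i1 <- renderImage(renderDRR(v1, cam, tf, 0.5))
  i2 <- renderImage(renderDRR(v2, cam, tf, 0.5))
  expect_true(all(i2 <= i1 + 1e-12))
})

test_that("semi-transparent accumulation reproduces hand-computed composites", {
  ## two slabs along the ray: (C=1, a=0.5) then (C=1, a=1)
  a <- array(0, c(2, 4, 4)); a[1, , ] <- 100; a[2, , ] <- 200
  v <- voxelVolume(a, spacing = c(1, 5, 5))
  cam <- camera("parallel", direction = c(1, 0, 0), center = c(1, 10, 10),
                imageSize = c(2L, 2L), pixelPitch = 3)
  tf <- transferFunction(hu = c(100, 200), shade = c(1, 1), opacity = c(0.5, 1))
  r <- renderSemiTransparent(v, cam, tf, step = 1)
  expect_equal(renderImage(r)[1, 1], 0.5 * 1 + 1 * 0.5)
  ## a fully opaque first sample hides everything behind it
  tfO <- transferFunction(hu = c(100, 200), shade = c(0.7, 0.1),
                          opacity = c(1, 1))
  expect_equal(renderImage(renderSemiTransparent(v, cam, tfO, 1))[1, 1], 0.7)
  ## all-transparent: zero image, far depth
  tfZ <- transferFunction(hu = c(100, 200), shade = c(1, 1), opacity = c(0, 0))
  rz <- renderSemiTransparent(v, cam, tfZ, 1)
  expect_true(all(renderImage(rz) == 0))
  expect_true(all(zBuffer(rz) == rz@far))
})

test_that("semi-transparent energy with unit shades never exceeds one", {
  set.seed(62)
  v <- voxelVolume(array(sample(0:300, 10^3, TRUE), c(10, 10, 10)), c(1, 1, 1))
  cam <- camera("parallel", direction = c(1, 0, 0), center = c(5, 5, 5),
                imageSize = c(8L, 8L), pixelPitch = 1.2)
  tf <- transferFunction(hu = c(0, 300), shade = c(1, 1), opacity = c(0, 0.9))
  r <- renderSemiTransparent(v, cam, tf, 0.5)
  expect_true(all(renderImage(r) <= 1 + 1e-12))
})

test_that("isosurface hits reconstruct a sphere's front hemisphere with radial normals", {
  n <- 48
  zc <- seq_len(n) - 0.5
  a <- array(0, c(n, n, n))
  for (s in seq_len(n))
    a[s, , ] <- ifelse(outer((zc - 24)^2, (zc - 24)^2, "+") +
                         (zc[s] - 24)^2 <= 15^2, 1000, 0)
  v <- voxelVolume(a, c(1, 1, 1))
  cam <- camera("parallel", direction = c(1, 0, 0), center = c(24, 24, 24),
                imageSize = c(9L, 9L), pixelPitch = 2)
  step <- 0.5
  r <- renderIsosurface(v, cam, 500, step)
  zb <- zBuffer(r)
  ## analytic first intersection for rays hitting within the sphere radius
  for (i in 1:9) for (j in 1:9) {
    oy <- (5 - i) * 2; ox <- (j - 5) * 2
    rho2 <- oy^2 + ox^2
    if (rho2 < 13^2) {               # keep clear of the silhouette
      tAnalytic <- -sqrt(15^2 - rho2)
      expect_lt(abs(zb[i, j] - tAnalytic), step + 0.6)  # within one step + voxelisation
    }
  }
  ## headlight shading: central hit is face-on (|g.L| ~ 1)
  expect_gt(renderImage(r)[5, 5], 0.95)
  ## constant volume: no crossing anywhere
  cvol <- voxelVolume(array(0, c(8, 8, 8)), c(1, 1, 1))
  rc <- renderIsosurface(cvol, cam, 500, 1)
  expect_true(all(renderImage(rc) == 0))
  expect_true(all(zBuffer(rc) == rc@far))
})

test_that("polygon compositing obeys both Z-buffer visibility rules", {
  ## slab occupying z > 10; first surface at z = 10 (t = 0 from the centre plane)
  a <- array(0, c(20, 20, 20)); a[11:20, , ] <- 1000
  v <- voxelVolume(a, c(1, 1, 1))
  cam <- camera("parallel", direction = c(1, 0, 0), center = c(10, 10, 10),
                imageSize = c(8L, 8L), pixelPitch = 2)
  r <- renderIsosurface(v, cam, 500, 0.25)
  mkpoly <- function(z, xmax) beamPolygon(
    rbind(c(z, -10, -10), c(z, 30, -10), c(z, 30, xmax), c(z, -10, xmax)),
    color = 5)
  ## polygon nearer than the surface: visible, takes its colour at w = 1
  front <- compositePolygons(r, list(mkpoly(5, 10)), cam, w = 1)
  expect_identical(sum(front == 5), 32L)    # exactly the covered half
  ## polygon behind the surface: hidden, image unchanged
  behind <- compositePolygons(r, list(mkpoly(15, 30)), cam, w = 1)
  expect_equal(behind, renderImage(r))
  ## half-occluded: slab edge covers x > 10, so only the x < 10 half of a
  ## deep polygon shows where the volume surface is absent
  aHalf <- array(0, c(20, 20, 20)); aHalf[11:20, , 11:20] <- 1000
  vH <- voxelVolume(aHalf, c(1, 1, 1))
  rH <- renderIsosurface(vH, cam, 500, 0.25)
  deep <- mkpoly(15, 30)                    # behind the slab surface
  imgH <- compositePolygons(rH, list(deep), cam, w = 1)
  leftCols <- imgH[, 1:4]; rightCols <- imgH[, 5:8]
  expect_true(all(leftCols == 5))           # no surface there: polygon visible
  expect_true(all(rightCols != 5))          # hidden behind the slab
  ## no polygons: identity
  expect_identical(compositePolygons(r, list(), cam), renderImage(r))
  ## blend weight: w = 0.5 mixes
  mix <- compositePolygons(r, list(mkpoly(5, 30)), cam, w = 0.5)
  expect_equal(mix[4, 4], 0.5 * renderImage(r)[4, 4] + 0.5 * 5)
})

test_that("images export to PGM and PNG", {
  td <- withr::local_tempdir()
  img <- matrix(seq(0, 1, length.out = 12), 3, 4)
  writeImage(img, file.path(td, "a.pgm"))
  lines <- readLines(file.path(td, "a.pgm"))
  expect_identical(lines[1], "P2")
  expect_identical(lines[2], "4 3")
  writeImage(img, file.path(td, "a.png"))
  expect_true(file.size(file.path(td, "a.png")) > 0)
})
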