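## Synthetic test volumes with exact ground truth.  Voxelisation rule
## everywhere: a voxel is foreground when its centre lies inside the
## analytic surface (centre inclusion).

#' Generate the verification phantom: a cube holding a grid of spheres
#'
#' A water-equivalent cube (default 120 mm on edge, scanned at 1 mm slice
#' thickness into 120 slices of 512 x 512 pixels) containing high-HU
#' spheres of the given diameter placed on a regular grid with constant
#' centre-to-centre pitch.  The returned ground truth holds the voxelised
#' sphere mask.
#'
#' @param spec a [PhantomSpec-class] with `kind = "cubic_spheres"`.
#' @return `list(volume = VoxelVolume, truth = GroundTruth)`.
#' @examples
#' spec <- phantomSpec("cubic_spheres", extent = c(20, 20, 20),
#'                     matrixSize = c(64L, 64L), sliceThickness = 2)
#' ph <- generateCubicPhantom(spec)
#' nSlices(ph$volume)   # ceil(20 / 2) = 10
#' @export
generateCubicPhantom <- function(spec) {
  validObject(spec)
  if (spec@kind != "cubic_spheres")
    ctsimStop("invalidParameter", "spec kind must be 'cubic_spheres'")
  nz <- as.integer(ceiling(spec@extent[1L] / spec@sliceThickness))
  nr <- spec@matrixSize[1L]; nc <- spec@matrixSize[2L]
  dz <- spec@sliceThickness
  dy <- spec@extent[2L] / nr; dx <- spec@extent[3L] / nc
  bgHU <- unname(spec@tissueHU["background"])
  spHU <- unname(spec@tissueHU["sphere"])
  if (is.na(bgHU)) bgHU <- 0
  if (is.na(spHU)) spHU <- 1000
  r <- spec@sphereDiameter / 2
  pitch <- spec@spherePitch
  centersAxis <- function(extent) {
    k <- floor(extent / pitch)
    if (k < 1L) return(numeric())
    span <- (k - 1) * pitch
    (extent - span) / 2 + (0:(k - 1)) * pitch
  }
  czs <- centersAxis(nz * dz); cys <- centersAxis(spec@extent[2L])
  cxs <- centersAxis(spec@extent[3L])
  yc <- (seq_len(nr) - 0.5) * dy
  xc <- (seq_len(nc) - 0.5) * dx
  vol <- array(bgHU, c(nz, nr, nc))
  mask <- array(0L, c(nz, nr, nc))
  for (s in seq_len(nz)) {
    zc <- (s - 0.5) * dz
    for (cz in czs) {
      dz2 <- r^2 - (zc - cz)^2
      if (dz2 <= 0) next
      rad <- sqrt(dz2)
      for (cy in cys) {
        rows <- which(abs(yc - cy) <= rad)
        if (!length(rows)) next
        for (cx in cxs) {
          cols <- which(abs(xc - cx) <= rad)
          if (!length(cols)) next
          sub <- outer((yc[rows] - cy)^2, (xc[cols] - cx)^2, "+") <= dz2
          if (any(sub)) {
            vslice <- vol[s, rows, cols]
            vslice[sub] <- spHU
            vol[s, rows, cols] <- vslice
            mslice <- mask[s, rows, cols]
            mslice[sub] <- 1L
            mask[s, rows, cols] <- mslice
          }
        }
      }
    }
  }
  if (spec@noiseSD > 0)
    vol <- vol + withSeed(spec@seed,
                          stats::rnorm(length(vol), sd = spec@noiseSD))
  sp3 <- c(dz, dy, dx)
  list(volume = voxelVolume(vol, spacing = sp3),
       truth = new("GroundTruth",
                   masks = list(spheres = binaryMask(mask, spacing = sp3))))
}

#' Generate a ground-truth thorax phantom
#'
#' An elliptic-cylinder soft-tissue body on an air background, holding two
#' ellipsoidal air-valued lungs (each a single 6-connected component) and a
#' bone-valued cylindrical spine.  HU defaults (air -1000, lung -800, soft
#' tissue 40, bone 700) are physically plausible and far enough apart that
#' threshold windows can be varied freely in tests.  Optional i.i.d.
#' Gaussian HU noise is added with the spec's seed, so generation is a pure
#' function of the spec.
#'
#' Ground-truth masks: `left_lung`, `right_lung` and `spine` are pairwise
#' disjoint; `body` is the external patient outline and therefore contains
#' the organs (the mask a skin/body segmentation should recover).
#'
#' @param spec a [PhantomSpec-class] with `kind = "thorax"`.
#' @return `list(volume = VoxelVolume, truth = GroundTruth)`.
#' @export
generateThorax <- function(spec) {
  validObject(spec)
  if (spec@kind != "thorax")
    ctsimStop("invalidParameter", "spec kind must be 'thorax'")
  nz <- as.integer(ceiling(spec@extent[1L] / spec@sliceThickness))
  nr <- spec@matrixSize[1L]; nc <- spec@matrixSize[2L]
  dz <- spec@sliceThickness
  dy <- spec@extent[2L] / nr; dx <- spec@extent[3L] / nc
  hu <- spec@tissueHU
  need <- c("air", "lung", "soft", "bone")
  if (!all(need %in% names(hu)))
    ctsimStop("invalidParameter", "thorax tissueHU must name air, lung, soft, bone")

  extZ <- nz * dz; extY <- spec@extent[2L]; extX <- spec@extent[3L]
  cy <- extY / 2; cx <- extX / 2
  ## proportional anatomy: scale with the in-plane extents
  bodyA <- 0.26 * extY          # body semi-axis, y (anterior-posterior)
  bodyB <- 0.36 * extX          # body semi-axis, x (left-right)
  lungAy <- 0.145 * extY; lungAx <- 0.115 * extX
  lungAz <- 0.35 * extZ
  lungCz <- extZ / 2; lungCy <- cy - 0.03 * extY
  lungOff <- 0.16 * extX        # lung centre offset from midline
  spineR <- 0.04 * extY                # spine radius
  spineCy <- cy + 0.18 * extY

  yc <- (seq_len(nr) - 0.5) * dy
  xc <- (seq_len(nc) - 0.5) * dx
  yg <- matrix(yc, nr, nc); xg <- matrix(xc, nr, nc, byrow = TRUE)
  body2d <- ((yg - cy) / bodyA)^2 + ((xg - cx) / bodyB)^2 <= 1
  spine2d <- (yg - spineCy)^2 + (xg - cx)^2 <= spineR^2
  lungBase <- function(side) {
    lcx <- cx + side * lungOff
    list(cy = lungCy, cx = lcx)
  }

  vol <- array(unname(hu["air"]), c(nz, nr, nc))
  mBody <- array(0L, c(nz, nr, nc)); mSpine <- array(0L, c(nz, nr, nc))
  mLL <- array(0L, c(nz, nr, nc)); mRL <- array(0L, c(nz, nr, nc))
  left <- lungBase(-1); right <- lungBase(+1)
  for (s in seq_len(nz)) {
    zc <- (s - 0.5) * dz
    slice <- matrix(unname(hu["air"]), nr, nc)
    slice[body2d] <- unname(hu["soft"])
    zf <- 1 - ((zc - lungCz) / lungAz)^2
    if (zf > 0) {
      ay <- lungAy * sqrt(zf); ax <- lungAx * sqrt(zf)
      ll <- ((yg - left$cy) / ay)^2 + ((xg - left$cx) / ax)^2 <= 1
      rl <- ((yg - right$cy) / ay)^2 + ((xg - right$cx) / ax)^2 <= 1
      slice[ll] <- unname(hu["lung"])
      slice[rl] <- unname(hu["lung"])
      mLL[s, , ] <- as.integer(ll)
      mRL[s, , ] <- as.integer(rl)
    }
    slice[spine2d] <- unname(hu["bone"])
    vol[s, , ] <- slice
    mBody[s, , ] <- as.integer(body2d)
    mSpine[s, , ] <- as.integer(spine2d)
  }
  ## spine overrides lungs where they would overlap (they do not by default)
  mLL[mSpine == 1L] <- 0L; mRL[mSpine == 1L] <- 0L
  if (spec@noiseSD > 0)
    vol <- vol + withSeed(spec@seed,
                          stats::rnorm(length(vol), sd = spec@noiseSD))
  sp3 <- c(dz, dy, dx)
  list(volume = voxelVolume(vol, spacing = sp3),
       truth = new("GroundTruth", masks = list(
         left_lung = binaryMask(mLL, spacing = sp3),
         right_lung = binaryMask(mRL, spacing = sp3),
         spine = binaryMask(mSpine, spacing = sp3),
         body = binaryMask(mBody, spacing = sp3))))
}
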