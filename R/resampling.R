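#' Linear-family interpolation
#'
#' The linear interpolation kernel is the unit triangle
#' `h(x) = 1 - |x|` for `|x| <= 1`, 0 beyond — a reasonably good low-pass
#' filter.  `lerp()` blends two samples, `bilerp()` four (a pixel cell),
#' `trilerp()` eight (a voxel cell).  Corner naming follows the `p_xyz`
#' digit convention: the first digit is the x offset, then y, then z, so the
#' weight of `p101` is `x (1-y) z`.  All weights sum to 1, so the result is
#' a convex combination of the corner values; extrapolation is refused.
#'
#' @param p0,p1 the two samples bracketing the 1D position.
#' @param x,y,z fractional coordinates in `[0, 1]`.
#' @return the interpolated scalar.
#' @examples
#' lerp(10, 20, 0.5)                            # 15
#' bilerp(0, 0, 0, 1, 0.5, 0.5)                 # 0.25
#' trilerp(0, 0, 0, 0, 0, 0, 0, 1, 0.5, 0.5, 0.5)  # 0.125
#' @export
lerp <- function(p0, p1, x) {
  .checkFrac(x)
  (1 - x) * p0 + x * p1
}

#' @rdname lerp
#' @param p00,p01,p10,p11 corner samples, digits (x, y).
#' @export
bilerp <- function(p00, p01, p10, p11, x, y) {
  .checkFrac(x); .checkFrac(y)
  (1 - x) * (1 - y) * p00 + (1 - x) * y * p01 +
    x * (1 - y) * p10 + x * y * p11
}

#' @rdname lerp
#' @param p000,p001,p010,p011,p100,p101,p110,p111 corner samples,
#'   digits (x, y, z).
#' @export
trilerp <- function(p000, p001, p010, p011, p100, p101, p110, p111,
                    x, y, z) {
  .checkFrac(x); .checkFrac(y); .checkFrac(z)
  (1 - x) * (1 - y) * (1 - z) * p000 + x * (1 - y) * (1 - z) * p100 +
    (1 - x) * y * (1 - z) * p010 + x * y * (1 - z) * p110 +
    (1 - x) * (1 - y) * z * p001 + x * (1 - y) * z * p101 +
    (1 - x) * y * z * p011 + x * y * z * p111
}

.checkFrac <- function(x) {
  if (any(x < 0 | x > 1))
    ctsimStop("invalidParameter",
              "interpolation coordinates must lie in [0, 1] (no extrapolation)")
}

## Vectorised trilinear sampling of a volume at world (z, y, x) mm points.
## `outside = "zero"` returns `fill` for points beyond the volume's world
## extent (half-open voxel cells); within the extent, coordinates are edge-
## clamped to the voxel-centre hull, so border values continue to the cell
## boundary.  Returns a numeric vector.
trilerpVolume <- function(volume, pts, outside = c("clamp", "zero"),
                          fill = 0) {
  outside <- match.arg(outside)
  v <- volume@data
  d <- dim(v)
  sp <- volume@spacing; or <- volume@origin
  res <- numeric(nrow(pts))
  inside <- rep(TRUE, nrow(pts))
  if (outside == "zero") {
    for (ax in 1:3)
      inside <- inside & pts[, ax] >= or[ax] &
        pts[, ax] <= or[ax] + d[ax] * sp[ax]
    res[!inside] <- fill
    if (!any(inside)) return(res)
  }
  u <- matrix(0, sum(inside), 3L)
  for (ax in 1:3)
    u[, ax] <- pmin(pmax((pts[inside, ax] - or[ax]) / sp[ax] - 0.5, 0),
                    d[ax] - 1)
  i0 <- pmin(floor(u), matrix(rep(d - 1 - (d > 1), each = nrow(u)), ncol = 3L))
  fr <- u - i0
  i0 <- i0 + 1L                           # 1-based lower corner
  i1 <- pmin(i0 + 1L, matrix(rep(d, each = nrow(u)), ncol = 3L))
  g <- function(a, b, cc) v[cbind(a, b, cc)]
  z0 <- i0[, 1L]; z1 <- i1[, 1L]; fz <- fr[, 1L]
  y0 <- i0[, 2L]; y1 <- i1[, 2L]; fy <- fr[, 2L]
  x0 <- i0[, 3L]; x1 <- i1[, 3L]; fx <- fr[, 3L]
  val <-
    (1 - fx) * (1 - fy) * (1 - fz) * g(z0, y0, x0) +
    fx * (1 - fy) * (1 - fz) * g(z0, y0, x1) +
    (1 - fx) * fy * (1 - fz) * g(z0, y1, x0) +
    fx * fy * (1 - fz) * g(z0, y1, x1) +
    (1 - fx) * (1 - fy) * fz * g(z1, y0, x0) +
    fx * (1 - fy) * fz * g(z1, y0, x1) +
    (1 - fx) * fy * fz * g(z1, y1, x0) +
    fx * fy * fz * g(z1, y1, x1)
  res[inside] <- val
  res
}

#' Resample a volume to isotropic voxels
#'
#' CT stacks usually have coarser spacing between slices than within them,
#' so voxels are not cubic and renderings are distorted until the volume is
#' interpolated onto an isotropic grid.  The new grid covers the same world
#' extent (the voxel count per axis is `round(extent / targetSpacing)`) and
#' values are trilinearly interpolated at the new voxel centres; samples
#' past the outermost original voxel centres take the edge value.
#'
#' @param volume a [VoxelVolume-class].
#' @param targetSpacing isotropic voxel size in mm (> 0); must not be
#'   coarser than half the smallest volume extent.
#' @return a [VoxelVolume-class] with spacing `c(t, t, t)`.
#' @export
resampleToIsotropic <- function(volume, targetSpacing) {
  if (targetSpacing <= 0)
    ctsimStop("invalidParameter", "targetSpacing must be > 0")
  d <- dim(volume@data)
  ext <- d * volume@spacing
  if (any(targetSpacing > ext / 2))
    ctsimStop("invalidParameter",
              "targetSpacing coarser than half the volume extent (degenerate)")
  nNew <- pmax(2L, as.integer(round(ext / targetSpacing)))
  or <- volume@origin
  zc <- or[1L] + (seq_len(nNew[1L]) - 0.5) * targetSpacing
  yc <- or[2L] + (seq_len(nNew[2L]) - 0.5) * targetSpacing
  xc <- or[3L] + (seq_len(nNew[3L]) - 0.5) * targetSpacing
  grid <- as.matrix(expand.grid(z = zc, y = yc, x = xc))
  vals <- trilerpVolume(volume, grid, outside = "clamp")
  voxelVolume(array(vals, nNew), spacing = rep(targetSpacing, 3L),
              origin = or, bits = volume@bits)
}
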