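## Semi-automatic boundary-tracking segmentation: the user supplies one seed
## point; the package thresholds each slice, handles seeds that fall outside
## the organ (relocation through region growing) or inside next to small
## bright spots (small-region suppression), traces the organ boundary with
## Moore 8-neighbour following, and propagates the seed slice to slice.

## Clockwise Moore neighbourhood, screen coordinates (row down):
## N, NE, E, SE, S, SW, W, NW.
.MOORE <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L,
                   0L, -1L, -1L, -1L), ncol = 2L, byrow = TRUE)

## Moore-neighbour boundary following with Jacob's stopping criterion on a
## padded logical matrix; returns the traced pixel chain (k x 2, unpadded
## 1-based (row, col)).  The chain is closed implicitly (last connects to
## first); every traced pixel is an object pixel.
.traceBoundaryPx <- function(m, start) {
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) ctsimStop("noObject", "mask contains no object pixels")
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  s <- as.integer(start) + 1L              # padded coords

  ## probe rays in +x, +y, -x, -y order until a sharp edge is found
  dirs <- list(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))
  b <- NULL; back <- NULL
  for (d in dirs) {
    cur <- s
    if (p[cur[1L], cur[2L]]) {             # seed on object: walk to the edge
      repeat {
        nxt <- cur + d
        if (!p[nxt[1L], nxt[2L]]) { b <- cur; back <- nxt; break }
        cur <- nxt
      }
      break
    } else {                               # seed on background: walk to object
      repeat {
        nxt <- cur + d
        if (nxt[1L] < 1L || nxt[1L] > nr + 2L || nxt[2L] < 1L ||
            nxt[2L] > nc + 2L) break
        if (p[nxt[1L], nxt[2L]]) { b <- nxt; back <- cur; break }
        cur <- nxt
      }
      if (!is.null(b)) break
    }
  }
  if (is.null(b))
    ctsimStop("noObject", "no object found along the probe rays from the seed")

  neighborIndex <- function(b, q) {
    d <- q - b
    which(.MOORE[, 1L] == d[1L] & .MOORE[, 2L] == d[2L])
  }
  b0 <- b; b1 <- NULL
  pts <- matrix(0L, 256L, 2L); npts <- 0L
  push <- function(q) {
    npts <<- npts + 1L
    if (npts > nrow(pts)) pts <<- rbind(pts, matrix(0L, nrow(pts), 2L))
    pts[npts, ] <<- q
  }
  push(b)
  maxIter <- 8L * (nr * nc) + 64L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter) ctsimStop("internal", "boundary trace failed to close")
    start_i <- neighborIndex(b, back)
    found <- FALSE
    prev <- back
    for (k in seq_len(8L)) {
      idx <- ((start_i - 1L + k) %% 8L) + 1L
      q <- b + .MOORE[idx, ]
      if (p[q[1L], q[2L]]) { found <- TRUE; break }
      prev <- q
    }
    if (!found) break                       # isolated single pixel
    ## Jacob's criterion: stop when the first traced move (b0 -> b1) is
    ## about to repeat, i.e. the walk has closed the loop
    if (!is.null(b1) && all(b == b0) && all(q == b1)) break
    if (is.null(b1)) b1 <- q
    b <- q; back <- prev
    push(b)
  }
  if (npts > 1L && all(pts[npts, ] == pts[1L, ])) npts <- npts - 1L
  pts[seq_len(npts), , drop = FALSE] - 1L   # back to unpadded coords
}

#' Trace the boundary of an object region
#'
#' Follows the region boundary with Moore 8-neighbour following, keeping the
#' object consistently on one side, until the trace returns to its starting
#' state (Jacob's stopping criterion).  The starting pixel is found by
#' casting rays from `start` in the four axial directions (+x, +y, -x, -y
#' order) until an object edge is hit, so `start` may sit inside the region
#' or in the background next to it.  Every returned point is an object pixel
#' 4-adjacent to the background; the contour is closed (the last point
#' connects back to the first).
#'
#' @param mask a 2D [BinaryMask-class] with at least one object pixel.
#' @param start integer(2) (row, col) pixel index, or a [SeedPoint-class]
#'   (its row/col are used).
#' @return a closed [Contour-class]; points are pixel centres in mm
#'   (using the mask spacing/origin).
#' @export
trackBoundary <- function(mask, start) {
  m <- .mask2d(mask)
  if (is(start, "SeedPoint")) start <- start@position[2:3]
  start <- as.integer(start)
  if (any(start < 1L) || start[1L] > nrow(m) || start[2L] > ncol(m))
    ctsimStop("invalidParameter", "start pixel outside the mask")
  chain <- .traceBoundaryPx(m, start)
  contour2D(.chainToMm(chain, mask), closed = TRUE)
}

.mask2d <- function(mask) {
  if (!is(mask, "BinaryMask") || length(dim(mask@data)) != 2L)
    ctsimStop("invalidParameter", "a 2D BinaryMask is required")
  mask@data != 0L
}

.chainToMm <- function(chain, mask) {
  sp <- mask@spacing; or <- mask@origin
  cbind(y = mmFromPx(chain[, 1L], sp[1L], or[1L]),
        x = mmFromPx(chain[, 2L], sp[2L], or[2L]))
}

#' Relocate a background seed into the nearest object region
#'
#' When the user's starting point lies in the background, a region-growing
#' pass expands the background region around the seed until it first touches
#' an object region; the returned pixel is strictly interior to that region
#' (all four axial neighbours are object), so subsequent boundary tracking
#' cannot start from an unstable edge position.  A seed already inside an
#' object region is returned unchanged.
#'
#' @param mask a 2D [BinaryMask-class] with at least one object pixel.
#' @param seed integer(2) (row, col) or [SeedPoint-class].
#' @return integer(2) (row, col) of a pixel inside the found region.
#' @export
relocateSeedOutside <- function(mask, seed) {
  m <- .mask2d(mask)
  if (is(seed, "SeedPoint")) seed <- seed@position[2:3]
  seed <- as.integer(seed)
  if (!any(m)) ctsimStop("noObject", "mask contains no object pixels")
  if (m[seed[1L], seed[2L]]) return(seed)
  region <- matrix(FALSE, nrow(m), ncol(m))
  region[seed[1L], seed[2L]] <- TRUE
  repeat {
    grown <- dilate4(region)
    touched <- grown & m
    if (any(touched)) {
      ## first touched object pixel in reading order (row-major)
      idx <- which(t(touched))[1L]
      tc <- c(((idx - 1L) %/% ncol(m)) + 1L, ((idx - 1L) %% ncol(m)) + 1L)
      lab <- label8(m)
      comp <- lab == lab[tc[1L], tc[2L]]
      inter <- interior4(comp)
      if (!any(inter)) return(tc)          # thin region: no strict interior
      w <- which(inter, arr.ind = TRUE)
      d2 <- (w[, 1L] - tc[1L])^2 + (w[, 2L] - tc[2L])^2
      best <- order(d2, w[, 1L], w[, 2L])[1L]
      return(as.integer(w[best, ]))
    }
    nxt <- grown & !m
    if (all(nxt == region)) ctsimStop("noObject", "no object reachable from seed")
    region <- nxt
  }
}

#' Suppress small object regions
#'
#' Every 8-connected object component whose in-plane area is at most
#' `maxAreaCm2` is set to background.  This is the "inside point" safeguard:
#' small bright spots inside an organ (empirically below about 6 cm^2) must
#' not capture the boundary tracker.
#'
#' @param mask a 2D [BinaryMask-class]; its (dy, dx) spacing defines the
#'   pixel area.
#' @param maxAreaCm2 removal threshold in cm^2 (default 6).
#' @return a [BinaryMask-class] with small components removed (may be empty).
#' @export
removeSmallRegions <- function(mask, maxAreaCm2 = 6) {
  m <- .mask2d(mask)
  pxCm2 <- mask@spacing[1L] * mask@spacing[2L] / 100
  lab <- label8(m)
  k <- max(lab)
  if (k > 0L) {
    areas <- tabulate(lab[lab > 0L], k) * pxCm2
    drop <- which(areas <= maxAreaCm2)
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  binaryMask(m, spacing = mask@spacing, origin = mask@origin)
}

#' Seeded region growing
#'
#' Grows a 6-connected voxel region from a seed.  With
#' `compare = "adjacent"` (the literal reading of the growth rule) a voxel
#' joins when its grey-level difference to an already-accepted adjacent voxel
#' is within `delta`; the accepted set is the order-independent closure of
#' that relation.  With `compare = "seed"` the difference is taken against
#' the seed voxel's value instead.  `delta = 0` grows the seed's maximal
#' constant-value component.
#'
#' @param volume a [VoxelVolume-class].
#' @param seed [SeedPoint-class] or integer(3) (slice, row, col).
#' @param delta grey-level tolerance in HU (inclusive: a difference equal to
#'   `delta` still joins).
#' @param compare `"adjacent"` or `"seed"`.
#' @return a 3D [BinaryMask-class] congruent with the volume.
#' @export
regionGrow <- function(volume, seed, delta, compare = c("adjacent", "seed")) {
  compare <- match.arg(compare)
  if (is(seed, "SeedPoint")) seed <- seed@position
  seed <- as.integer(seed)
  v <- volume@data
  d <- dim(v)
  if (any(seed < 1L) || any(seed > d))
    ctsimStop("invalidParameter", "seed outside the volume")
  if (delta < 0) ctsimStop("invalidParameter", "delta must be >= 0")
  acc <- array(FALSE, d)
  acc[seed[1L], seed[2L], seed[3L]] <- TRUE
  if (compare == "seed") {
    eligible <- abs(v - v[seed[1L], seed[2L], seed[3L]]) <= delta
    repeat {
      new <- .dilate6(acc) & eligible & !acc
      if (!any(new)) break
      acc <- acc | new
    }
  } else {
    repeat {
      new <- .growAdjacent(acc, v, delta) & !acc
      if (!any(new)) break
      acc <- acc | new
    }
  }
  binaryMask(acc, spacing = volume@spacing, origin = volume@origin)
}

.dilate6 <- function(a) {
  d <- dim(a); out <- a
  out[-1, , ] <- out[-1, , ] | a[-d[1L], , ]
  out[-d[1L], , ] <- out[-d[1L], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -d[2L], ]
  out[, -d[2L], ] <- out[, -d[2L], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -d[3L]]
  out[, , -d[3L]] <- out[, , -d[3L]] | a[, , -1]
  out
}

## one sweep of the adjacent-comparison growth rule: voxels having at least
## one accepted 6-neighbour whose value differs by <= delta
.growAdjacent <- function(acc, v, delta) {
  d <- dim(v)
  out <- array(FALSE, d)
  ok <- function(sliceTo, sliceFrom) {
    abs(v[sliceTo[[1L]], sliceTo[[2L]], sliceTo[[3L]], drop = FALSE] -
        v[sliceFrom[[1L]], sliceFrom[[2L]], sliceFrom[[3L]], drop = FALSE]) <= delta
  }
  i1 <- seq_len(d[1L]); i2 <- seq_len(d[2L]); i3 <- seq_len(d[3L])
  ## z neighbours
  to <- list(i1[-1L], i2, i3); fr <- list(i1[-d[1L]], i2, i3)
  out[to[[1L]], , ] <- out[to[[1L]], , ] |
    (acc[fr[[1L]], , , drop = FALSE] & ok(to, fr))
  out[fr[[1L]], , ] <- out[fr[[1L]], , ] |
    (acc[to[[1L]], , , drop = FALSE] & ok(fr, to))
  ## y neighbours
  to <- list(i1, i2[-1L], i3); fr <- list(i1, i2[-d[2L]], i3)
  out[, to[[2L]], ] <- out[, to[[2L]], ] |
    (acc[, fr[[2L]], , drop = FALSE] & ok(to, fr))
  out[, fr[[2L]], ] <- out[, fr[[2L]], ] |
    (acc[, to[[2L]], , drop = FALSE] & ok(fr, to))
  ## x neighbours
  to <- list(i1, i2, i3[-1L]); fr <- list(i1, i2, i3[-d[3L]])
  out[, , to[[3L]]] <- out[, , to[[3L]]] |
    (acc[, , fr[[3L]], drop = FALSE] & ok(to, fr))
  out[, , fr[[3L]]] <- out[, , fr[[3L]]] |
    (acc[, , to[[3L]], drop = FALSE] & ok(fr, to))
  out
}

#' Segment a structure through the volume from one seed point
#'
#' The per-slice pipeline: threshold by the HU window; optional in-plane
#' majority smoothing of the binary mask; suppression of regions at most
#' `minRegionAreaCm2`; seed resolution (background seeds are relocated into
#' the nearest region, seeds on a suppressed small region are retargeted to
#' the largest surviving region); Moore boundary tracking; polygon fill;
#' optional point decimation of the emitted contour.  The seed for the next
#' slice is the centroid of the current slice's region (with relocation as
#' fallback when the centroid falls outside a concave region), and tracking
#' proceeds in both stack directions until the structure vanishes.
#'
#' On slices after the first, a candidate region must overlap the previous
#' slice's region; this keeps the tracker from jumping to a different organ
#' that happens to share the HU window once the structure has ended.
#'
#' @param volume a [VoxelVolume-class].
#' @param seed [SeedPoint-class] or integer(3) (slice, row, col).
#' @param params a [SegmentationParams-class].
#' @param structure name recorded on the returned contour set.
#' @return a [SegmentationResult-class]: per-slice contours plus the filled
#'   3D mask (rasterised from exactly the returned contours).
#' @examples
#' ph <- generateThorax(phantomSpec("thorax", extent = c(64, 96, 96),
#'   sliceThickness = 4, matrixSize = c(64L, 64L)))
#' sr <- segmentStructure(ph$volume, seedPoint(c(8, 32, 20)),
#'   segmentationParams(huWindow = c(-950, -300)))
#' structureContours(sr)
#' @export
segmentStructure <- function(volume, seed, params = segmentationParams(),
                             structure = "structure") {
  if (is(seed, "SeedPoint")) seed <- seed@position
  seed <- as.integer(seed)
  d <- dim(volume@data)
  if (any(seed < 1L) || any(seed > d))
    ctsimStop("invalidParameter", "seed outside the volume")
  lo <- params@huWindow[1L]; hi <- params@huWindow[2L]
  sp <- volume@spacing; or <- volume@origin
  sp2 <- sp[2:3]; or2 <- or[2:3]
  warnings <- character()

  sliceMask <- function(s) {
    m <- volume@data[s, , ] >= lo & volume@data[s, , ] <= hi
    if (params@smoothSize > 1L)   # majority vote within the box
      m <- smoothImage(m + 0, params@smoothSize) >= 0.5
    m
  }
  pxCm2 <- sp2[1L] * sp2[2L] / 100

  processSlice <- function(s, seedPx, prevFill) {
    m <- sliceMask(s)
    lab <- label8(m)
    k <- max(lab)
    if (k == 0L) return(NULL)
    areas <- tabulate(lab[lab > 0L], k) * pxCm2
    keep <- areas > params@minRegionAreaCm2
    if (!any(keep)) return(NULL)
    clean <- matrix(FALSE, nrow(m), ncol(m))
    clean[lab > 0L] <- keep[lab[lab > 0L]]
    labSeed <- lab[seedPx[1L], seedPx[2L]]
    if (labSeed > 0L && keep[labSeed]) {
      target <- labSeed
    } else if (labSeed > 0L) {
      ## seed on a suppressed small region: largest surviving region wins
      target <- which(keep)[which.max(areas[keep])]
    } else {
      cm <- binaryMask(clean, spacing = sp2, origin = or2)
      seedPx <- relocateSeedOutside(cm, seedPx)
      target <- lab[seedPx[1L], seedPx[2L]]
    }
    comp <- lab == target
    if (!is.null(prevFill) && !any(comp & prevFill)) return(NULL)
    start <- if (comp[seedPx[1L], seedPx[2L]]) seedPx else
      which(comp, arr.ind = TRUE)[1L, ]
    chain <- .traceBoundaryPx(comp, as.integer(start))
    if (params@decimatePercent > 0 && nrow(chain) >= 4L) {
      cc <- decimateContour(contour2D(chain, closed = TRUE),
                            params@decimatePercent)
      chain <- cc@points
    }
    fill <- rasterizePolygonPx(chain[, 1L], chain[, 2L], dim(m))
    ctr <- round(colMeans(which(fill, arr.ind = TRUE)))
    ctr <- pmin(pmax(as.integer(ctr), 1L), dim(m))
    list(chain = chain, fill = fill, centroid = ctr)
  }

  first <- processSlice(seed[1L], seed[2:3], NULL)
  if (is.null(first))
    ctsimStop("structureAbsent", sprintf("no structure at seed slice %d", seed[1L]))
  results <- vector("list", d[1L])
  results[[seed[1L]]] <- first

  for (dir in c(1L, -1L)) {
    prev <- first
    s <- seed[1L] + dir
    while (s >= 1L && s <= d[1L]) {
      cur <- processSlice(s, prev$centroid, prev$fill)
      if (is.null(cur)) {
        warnings <- c(warnings,
          sprintf("structure ends before slice %d (direction %+d)", s, dir))
        break
      }
      results[[s]] <- cur
      prev <- cur
      s <- s + dir
    }
  }

  maskData <- array(0L, d)
  contours <- list()
  for (s in seq_len(d[1L])) {
    r <- results[[s]]
    if (is.null(r)) next
    maskData[s, , ] <- as.integer(r$fill)
    pts <- cbind(y = mmFromPx(r$chain[, 1L], sp2[1L], or2[1L]),
                 x = mmFromPx(r$chain[, 2L], sp2[2L], or2[2L]))
    contours[[length(contours) + 1L]] <- contour2D(pts, slice = s, closed = TRUE)
  }
  new("SegmentationResult",
      contours = contourSet(contours, structure = structure,
                            sliceSpacing = sp[1L]),
      mask = binaryMask(maskData, spacing = sp, origin = or),
      warnings = warnings)
}
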