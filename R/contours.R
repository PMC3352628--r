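#' Contour area in cm^2
#'
#' Shoelace polygon area (absolute value) of a closed contour whose points
#' are in mm; degenerate contours with fewer than 3 points have zero area.
#'
#' @param contour a closed [Contour-class].
#' @return area in cm^2.
#' @examples
#' sq <- contour2D(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0)))
#' contourArea(sq)        # 1 cm^2
#' @export
contourArea <- function(contour) {
  if (!contour@closed)
    ctsimStop("invalidParameter", "area is defined for closed contours only")
  p <- contour@points
  if (nrow(p) < 3L) return(0)
  abs(signedArea(p)) / 100
}

#' Contour periphery in cm
#'
#' Sum of consecutive point distances (mm), plus the closing segment for a
#' closed contour, converted to cm.
#'
#' @param contour a [Contour-class] with at least 2 points.
#' @return periphery in cm.
#' @export
contourPeriphery <- function(contour) {
  p <- contour@points
  if (nrow(p) < 2L) return(0)
  seg <- sqrt(rowSums(diff(p)^2))
  tot <- sum(seg)
  if (contour@closed) tot <- tot + sqrt(sum((p[1L, ] - p[nrow(p), ])^2))
  tot / 10
}

#' Decimate a contour's point sequence
#'
#' Removes `kPercent`% of the ordered points by uniform stride, always
#' retaining the first point: of `N` input points exactly
#' `floor(N * (1 - k/100))` survive, as an ordered subsequence of the input.
#' Shape is preserved "without loss of general presentation"; closedness is
#' preserved.
#'
#' @param contour a [Contour-class] with at least 4 points.
#' @param kPercent removal percentage, `0 <= k < 100`.
#' @return the decimated [Contour-class].
#' @examples
#' nrow(decimateContour(contour2D(cbind(sin(1:530), cos(1:530))), 20)@points)
#' # 424, as floor(530 * 0.8)
#' @export
decimateContour <- function(contour, kPercent) {
  if (kPercent < 0 || kPercent >= 100)
    ctsimStop("invalidParameter", "kPercent must be in [0, 100)")
  p <- contour@points
  N <- nrow(p)
  if (N < 4L) ctsimStop("invalidParameter", "contour must have >= 4 points")
  m <- floor(N * (1 - kPercent / 100))
  if (contour@closed && m < 3L)
    ctsimStop("invalidParameter", "decimation would leave < 3 points of a closed contour")
  idx <- floor((0:(m - 1L)) * N / m) + 1L
  contour2D(p[idx, , drop = FALSE], slice = contour@slice,
            closed = contour@closed)
}

## Normalise winding to counter-clockwise in (y, x) mm coordinates.
.normalizeOrientation <- function(contour) {
  if (signedArea(contour@points) < 0)
    contour@points <- contour@points[nrow(contour@points):1L, , drop = FALSE]
  contour
}

## Resample a closed contour to `sectors` equiangular points about its
## (shoelace) centroid: for each sector angle, the point where the ray from
## the centroid leaves the polygon (outermost edge intersection).
.resampleEquiangular <- function(contour, sectors) {
  p <- contour@points
  n <- nrow(p)
  if (n < 3L || abs(signedArea(p)) < 1e-12)
    ctsimStop("degenerateContour", "zero-area contour cannot be resampled")
  y <- p[, 1L]; x <- p[, 2L]
  j <- c(2:n, 1L)
  a2 <- x * y[j] - x[j] * y
  A <- sum(a2) / 2
  cy <- sum((y + y[j]) * a2) / (6 * A)
  cx <- sum((x + x[j]) * a2) / (6 * A)
  th <- 2 * pi * (0:(sectors - 1L)) / sectors
  dy <- sin(th); dx <- cos(th)
  out <- matrix(NA_real_, sectors, 2L)
  ey <- y[j] - y; ex <- x[j] - x
  for (k in seq_len(sectors)) {
    ## ray (cx,cy) + t (dx,dy) against each edge, t > 0, s in [0,1)
    den <- dx[k] * (-ey) - dy[k] * (-ex)
    s <- ((cy - y) * (-dx[k]) - (cx - x) * (-dy[k])) / den
    t <- (ey * (cx - x) - ex * (cy - y)) / den
    ## s tolerance: a ray through a shared vertex must hit one of the two
    ## incident edges despite rounding
    okEdge <- is.finite(s) & is.finite(t) & s >= -1e-9 & s <= 1 + 1e-9 &
      t > 1e-12
    if (!any(okEdge))
      ctsimStop("degenerateContour",
                "contour is not star-shaped about its centroid")
    r <- max(t[okEdge])
    out[k, ] <- c(cy + r * dy[k], cx + r * dx[k])
  }
  colnames(out) <- c("y", "x")
  out
}

#' Interpolate a contour between two key contours
#'
#' Both closed contours are normalised to the same winding direction and
#' resampled to `sectors` equiangular points about their centroids; matched
#' sector points on the two slices are joined into triangles, and the
#' contour on the intermediate plane at fraction `t` is the intersection of
#' the triangle sides with that plane — equivalently, the per-sector linear
#' blend `(1 - t) a_k + t b_k` of matched points.  `t = 0` and `t = 1`
#' reproduce the resampled inputs.
#'
#' The construction assumes each contour is star-shaped about its centroid
#' (true of the convex-to-mildly-concave organ outlines it is meant for).
#'
#' @param a,b closed [Contour-class] objects (key contours on two slices).
#' @param t interpolation fraction in `[0, 1]`.
#' @param sectors number of equiangular sectors (default 64).
#' @return the interpolated closed [Contour-class] (slice index `NA`).
#' @export
interpolateContours <- function(a, b, t, sectors = 64L) {
  if (!a@closed || !b@closed)
    ctsimStop("invalidParameter", "key contours must be closed")
  if (t < 0 || t > 1)
    ctsimStop("invalidParameter", "t must be within [0, 1]")
  pa <- .resampleEquiangular(.normalizeOrientation(a), sectors)
  pb <- .resampleEquiangular(.normalizeOrientation(b), sectors)
  contour2D((1 - t) * pa + t * pb, closed = TRUE)
}

#' Rasterise contours into a binary mask on a template grid
#'
#' Per-slice polygon rasterisation by pixel-centre inclusion, matching the
#' fill convention of [segmentStructure()]: a pixel belongs to the mask when
#' its centre lies inside the polygon or coincides with a polygon vertex.
#' Round-tripping a traced region through `trackBoundary()` and back
#' reproduces it.
#'
#' @param cs a [ContourSet-class]; points in mm.
#' @param template a [VoxelVolume-class] defining grid, spacing and origin.
#' @return a 3D [BinaryMask-class] congruent with `template`.
#' @export
contoursToMask <- function(cs, template) {
  d <- dim(template@data)
  sp <- template@spacing; or <- template@origin
  out <- array(0L, d)
  for (cc in cs@contours) {
    s <- cc@slice
    if (is.na(s) || s < 1L || s > d[1L])
      ctsimStop("outOfBounds", "contour slice outside the template volume")
    rowC <- pxFromMm(cc@points[, 1L], sp[2L], or[2L])
    colC <- pxFromMm(cc@points[, 2L], sp[3L], or[3L])
    if (min(rowC) < 0.5 - 1e-9 || max(rowC) > d[2L] + 0.5 + 1e-9 ||
        min(colC) < 0.5 - 1e-9 || max(colC) > d[3L] + 0.5 + 1e-9)
      ctsimStop("outOfBounds", "contour extends outside the template volume")
    fill <- rasterizePolygonPx(rowC, colC, d[2:3])
    out[s, , ] <- as.integer(out[s, , ] | fill)
  }
  binaryMask(out, spacing = sp, origin = or)
}

#' Write / read contour sets as JSON
#'
#' The schema maps structure name to a per-slice list of ordered
#' `[y_mm, x_mm]` points, with the slice spacing in a header.
#'
#' @param csList a [ContourSet-class] or list of them.
#' @param path output JSON file.
#' @return `path` invisibly (write); a list of [ContourSet-class] (read).
#' @export
writeContoursJSON <- function(csList, path) {
  if (is(csList, "ContourSet")) csList <- list(csList)
  payload <- list(slice_spacing_mm =
                    vapply(csList, function(cs) cs@sliceSpacing, numeric(1))[1L],
                  structures = list())
  for (cs in csList) {
    slices <- list()
    for (cc in cs@contours)
      slices[[as.character(cc@slice)]] <-
        list(closed = cc@closed, points = unname(cc@points))
    payload$structures[[cs@structure]] <- slices
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeContoursJSON
#' @export
readContoursJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  dz <- payload$slice_spacing_mm
  lapply(names(payload$structures), function(nm) {
    slices <- payload$structures[[nm]]
    contours <- lapply(names(slices), function(s) {
      contour2D(slices[[s]]$points, slice = as.integer(s),
                closed = isTRUE(slices[[s]]$closed))
    })
    contourSet(contours, structure = nm, sliceSpacing = dz)
  })
}

#' Export a contour set as CSV (slice, y_mm, x_mm)
#'
#' @param cs a [ContourSet-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeContoursCSV <- function(cs, path) {
  rows <- do.call(rbind, lapply(cs@contours, function(cc)
    data.frame(slice = cc@slice, y_mm = cc@points[, 1L], x_mm = cc@points[, 2L])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
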