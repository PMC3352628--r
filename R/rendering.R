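## Volume rendering: radiograph (transparent), semi-transparent front-to-back
## accumulation, gradient isosurface shading, and Z-buffer compositing of
## beam/block polygons over a rendered volume.

## Orthonormal camera frame: right and true-up vectors spanning the image
## plane, both perpendicular to the view direction.
.cameraFrame <- function(cam) {
  d <- cam@direction
  r <- cross3(d, normalize3(cam@up))
  if (sqrt(sum(r^2)) < 1e-9)
    ctsimStop("invalidParameter", "up vector parallel to view direction")
  r <- normalize3(r)
  u <- cross3(r, d)
  list(d = d, right = r, up = u)
}

## Per-pixel ray origins and directions.  Rays are returned row-major
## pixel-by-pixel: index = (col - 1) * nrow + row (column-major image
## storage).  Depth is measured along the ray from its origin (the image
## plane through `center` for parallel cameras, the source point for
## perspective cameras).
.makeRays <- function(cam) {
  fr <- .cameraFrame(cam)
  nr <- cam@imageSize[1L]; nc <- cam@imageSize[2L]
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  offR <- (grid$col - (nc + 1) / 2) * cam@pixelPitch
  offU <- ((nr + 1) / 2 - grid$row) * cam@pixelPitch
  planePts <- matrix(cam@center, nrow(grid), 3L, byrow = TRUE) +
    outer(offR, fr$right) + outer(offU, fr$up)
  if (cam@mode == "parallel") {
    origins <- planePts
    dirs <- matrix(fr$d, nrow(grid), 3L, byrow = TRUE)
  } else {
    origins <- matrix(cam@source, nrow(grid), 3L, byrow = TRUE)
    dirs <- planePts - origins
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  list(origins = origins, dirs = dirs, nr = nr, nc = nc, frame = fr)
}

## Ray / axis-aligned-box intersection (slab method), vectorised over rays.
## Returns tmin/tmax per ray (NA where the ray misses the box).
.rayBox <- function(origins, dirs, lo, hi) {
  n <- nrow(origins)
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  for (ax in 1:3) {
    o <- origins[, ax]; dd <- dirs[, ax]
    par <- abs(dd) < 1e-12
    t1 <- (lo[ax] - o) / dd
    t2 <- (hi[ax] - o) / dd
    lohi <- pmin(t1, t2); hilo <- pmax(t1, t2)
    tmin <- ifelse(par, ifelse(o >= lo[ax] & o <= hi[ax], tmin, NA), pmax(tmin, lohi))
    tmax <- ifelse(par, ifelse(o >= lo[ax] & o <= hi[ax], tmax, NA), pmin(tmax, hilo))
  }
  miss <- is.na(tmin) | is.na(tmax) | tmax <= tmin
  tmin[miss] <- NA; tmax[miss] <- NA
  list(tmin = tmin, tmax = tmax)
}

.volumeBox <- function(volume) {
  d <- dim(volume@data)
  list(lo = volume@origin, hi = volume@origin + d * volume@spacing)
}

.tfEval <- function(tf, what, hu) {
  v <- slot(tf, what)
  if (!length(v))
    ctsimStop("invalidParameter",
              sprintf("transfer function has no %s breakpoints", what))
  if (length(tf@hu) == 1L) return(rep(v, length(hu)))
  stats::approx(tf@hu, v, xout = hu, rule = 2)$y
}

.renderSetup <- function(volume, cam, step) {
  if (step <= 0) ctsimStop("invalidParameter", "step must be > 0")
  rays <- .makeRays(cam)
  box <- .volumeBox(volume)
  hit <- .rayBox(rays$origins, rays$dirs, box$lo, box$hi)
  far <- if (all(is.na(hit$tmax))) 1 else max(hit$tmax, na.rm = TRUE)
  c(rays, list(tmin = hit$tmin, tmax = hit$tmax, far = far))
}

#' Digitally reconstructed radiograph (transparent mode)
#'
#' Simulates an X-ray projection: along each pixel's ray the attenuation
#' coefficient `K` (from the transfer function) is integrated by midpoint
#' Riemann sum with trilinear sampling, and the pixel intensity is the
#' Beer–Lambert transmission `I = I0 * exp(-integral K dt)`.  Transparent
#' mode has no surface, so the depth buffer is the far-plane value
#' everywhere.
#'
#' @param volume a [VoxelVolume-class].
#' @param cam a [Camera-class] (parallel, or perspective for a Beam's Eye
#'   View geometry).
#' @param tf a [TransferFunction-class] with `attenuation` breakpoints
#'   (K in 1/mm).
#' @param step ray-march step in mm (> 0).
#' @param I0 incident intensity (default 1).
#' @return a [RenderResult-class].
#' @export
renderDRR <- function(volume, cam, tf, step, I0 = 1) {
  rs <- .renderSetup(volume, cam, step)
  n <- nrow(rs$origins)
  acc <- numeric(n)
  live <- !is.na(rs$tmin)
  if (any(live)) {
    nSteps <- ceiling((max(rs$tmax[live] - rs$tmin[live])) / step)
    for (k in seq_len(nSteps)) {
      t <- rs$tmin + (k - 0.5) * step
      active <- live & t < rs$tmax
      if (!any(active)) break
      pts <- rs$origins[active, , drop = FALSE] +
        rs$dirs[active, , drop = FALSE] * t[active]
      hu <- trilerpVolume(volume, pts, outside = "clamp")
      acc[active] <- acc[active] + .tfEval(tf, "attenuation", hu) * step
    }
  }
  img <- matrix(I0 * exp(-acc), rs$nr, rs$nc)
  new("RenderResult", image = img,
      zbuffer = matrix(rs$far, rs$nr, rs$nc), far = rs$far)
}

#' Semi-transparent volume rendering (front-to-back accumulation)
#'
#' Each sample contributes `C * alpha` weighted by the transparency
#' accumulated in front of it: `I = sum_i C_i alpha_i prod_{j<i}(1-alpha_j)`.
#' Samples are taken front to back with early ray termination once the
#' residual transparency drops below 1e-3.  The depth buffer records the
#' first sample at which accumulated opacity crosses 0.5.
#'
#' @inheritParams renderDRR
#' @param tf a [TransferFunction-class] with `shade` and `opacity`
#'   breakpoints (alpha is per sample, not per mm).
#' @return a [RenderResult-class].
#' @export
renderSemiTransparent <- function(volume, cam, tf, step) {
  rs <- .renderSetup(volume, cam, step)
  n <- nrow(rs$origins)
  img <- numeric(n)
  transp <- rep(1, n)
  zb <- rep(rs$far, n)
  live <- !is.na(rs$tmin)
  if (any(live)) {
    nSteps <- ceiling((max(rs$tmax[live] - rs$tmin[live])) / step)
    for (k in seq_len(nSteps)) {
      t <- rs$tmin + (k - 0.5) * step
      active <- live & t < rs$tmax & transp > 1e-3
      if (!any(active)) break
      pts <- rs$origins[active, , drop = FALSE] +
        rs$dirs[active, , drop = FALSE] * t[active]
      hu <- trilerpVolume(volume, pts, outside = "clamp")
      alpha <- .tfEval(tf, "opacity", hu)
      shade <- .tfEval(tf, "shade", hu)
      img[active] <- img[active] + shade * alpha * transp[active]
      newT <- transp[active] * (1 - alpha)
      crossed <- (1 - newT) >= 0.5 & zb[active] >= rs$far
      zb[active][crossed] <- t[active][crossed]
      transp[active] <- newT
    }
  }
  new("RenderResult", image = matrix(img, rs$nr, rs$nc),
      zbuffer = matrix(zb, rs$nr, rs$nc), far = rs$far)
}

#' Isosurface rendering with gradient (Lambertian) shading
#'
#' Along each ray the first crossing of the isovalue is located between
#' consecutive samples and refined by one linear sub-step; the surface
#' normal is the normalised central-difference gradient at the hit and the
#' pixel value is the Lambertian term `|g . L|`.  The depth buffer holds the
#' refined hit depth (far value where the ray misses the surface).
#'
#' @inheritParams renderDRR
#' @param isovalue HU level of the rendered surface.
#' @param light unit light direction (default: headlight along the view
#'   direction).
#' @return a [RenderResult-class].
#' @export
renderIsosurface <- function(volume, cam, isovalue, step, light = NULL) {
  rs <- .renderSetup(volume, cam, step)
  n <- nrow(rs$origins)
  if (is.null(light)) light <- cam@direction
  light <- normalize3(light)
  tHit <- rep(NA_real_, n)
  fPrev <- rep(NA_real_, n)
  live <- !is.na(rs$tmin)
  if (any(live)) {
    nSteps <- ceiling((max(rs$tmax[live] - rs$tmin[live])) / step)
    for (k in seq_len(nSteps)) {
      t <- rs$tmin + (k - 0.5) * step
      active <- live & t < rs$tmax & is.na(tHit)
      if (!any(active)) break
      pts <- rs$origins[active, , drop = FALSE] +
        rs$dirs[active, , drop = FALSE] * t[active]
      f <- trilerpVolume(volume, pts, outside = "clamp") - isovalue
      fp <- fPrev[active]
      firstInside <- is.na(fp) & f >= 0
      crossing <- !is.na(fp) & (sign(fp) != sign(f)) & fp != 0
      tStar <- rep(NA_real_, sum(active))
      tStar[firstInside] <- t[active][firstInside]
      if (any(crossing)) {
        frac <- fp[crossing] / (fp[crossing] - f[crossing])
        tStar[crossing] <- t[active][crossing] - step + frac * step
      }
      idx <- which(active)
      hitNow <- !is.na(tStar)
      tHit[idx[hitNow]] <- tStar[hitNow]
      fPrev[idx] <- f
    }
  }
  img <- numeric(n)
  zb <- rep(rs$far, n)
  hit <- which(!is.na(tHit))
  if (length(hit)) {
    zb[hit] <- tHit[hit]
    pts <- rs$origins[hit, , drop = FALSE] +
      rs$dirs[hit, , drop = FALSE] * tHit[hit]
    h <- 0.45 * min(volume@spacing)
    grad <- matrix(0, length(hit), 3L)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- h
      pp <- pts; pp[, ax] <- pp[, ax] + h
      pm <- pts; pm[, ax] <- pm[, ax] - h
      grad[, ax] <- (trilerpVolume(volume, pp, outside = "clamp") -
                     trilerpVolume(volume, pm, outside = "clamp")) / (2 * h)
    }
    gn <- sqrt(rowSums(grad^2))
    ok <- gn > 1e-12
    lam <- numeric(length(hit))
    lam[ok] <- abs(grad[ok, , drop = FALSE] %*% light)[, 1L] / gn[ok]
    img[hit] <- lam
  }
  new("RenderResult", image = matrix(img, rs$nr, rs$nc),
      zbuffer = matrix(zb, rs$nr, rs$nc), far = rs$far)
}

#' Composite beam/block polygons over a rendered volume
#'
#' Each planar polygon is scan-converted to a per-pixel depth `Z_P` by
#' intersecting the pixel rays with the polygon plane and testing the pixel
#' against the projected outline.  Depth increases away from the viewer, so
#' the polygon is visible at a pixel when it lies no deeper than the
#' volume's first surface (`Z_P <= Z_V`, ties drawn); there the pixel value
#' is blended, `(1 - w) * volume + w * polygon colour`.  Where the polygon
#' lies behind the surface it is hidden and the pixel is untouched.
#' Polygons seen edge-on (projection degenerate) are skipped with a warning
#' attribute.
#'
#' @param render a [RenderResult-class] from one of the volume renderers.
#' @param polys list of [BeamPolygon-class] objects.
#' @param cam the [Camera-class] used to produce `render`.
#' @param w blend weight of the polygon colour, in [0, 1] (default 0.5).
#' @return the composited image matrix; skipped polygons are reported in
#'   the `"skipped"` attribute.
#' @export
compositePolygons <- function(render, polys, cam, w = 0.5) {
  if (w < 0 || w > 1) ctsimStop("invalidParameter", "w must be in [0, 1]")
  img <- render@image
  if (!length(polys)) return(img)
  rays <- .makeRays(cam)
  fr <- rays$frame
  nr <- rays$nr; nc <- rays$nc
  skipped <- character()
  for (pi in seq_along(polys)) {
    poly <- polys[[pi]]
    v <- poly@vertices
    nrm <- .polyNormal(v)
    nrm <- nrm / sqrt(sum(nrm^2))
    ## project vertices to image coordinates
    if (cam@mode == "parallel") {
      q <- v - matrix(cam@center, nrow(v), 3L, byrow = TRUE)
      px <- (q %*% fr$right) / cam@pixelPitch + (nc + 1) / 2
      py <- (nr + 1) / 2 - (q %*% fr$up) / cam@pixelPitch
    } else {
      q <- v - matrix(cam@source, nrow(v), 3L, byrow = TRUE)
      depth <- q %*% fr$d
      if (any(depth <= 1e-9)) { skipped <- c(skipped,
        sprintf("polygon %d behind the source", pi)); next }
      f <- sum((cam@center - cam@source) * fr$d)
      scl <- as.numeric(f / depth)
      px <- (q %*% fr$right) * scl / cam@pixelPitch + (nc + 1) / 2
      py <- (nr + 1) / 2 - (q %*% fr$up) * scl / cam@pixelPitch
    }
    area2 <- abs(signedArea(cbind(py, px)))
    if (!is.finite(area2) || area2 < 1e-9) {
      skipped <- c(skipped, sprintf("polygon %d seen edge-on", pi)); next
    }
    denom <- rays$dirs %*% nrm
    tP <- ((matrix(v[1L, ], nrow(rays$origins), 3L, byrow = TRUE) -
            rays$origins) %*% nrm) / denom
    tP <- as.numeric(tP)
    tP[abs(as.numeric(denom)) < 1e-12] <- NA
    grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    inside <- pointInPolygon(grid$row, grid$col, as.numeric(py), as.numeric(px))
    zv <- as.numeric(render@zbuffer)
    visible <- inside & !is.na(tP) & tP <= zv + 1e-9
    img[cbind(grid$row[visible], grid$col[visible])] <-
      (1 - w) * img[cbind(grid$row[visible], grid$col[visible])] +
      w * poly@color
  }
  if (length(skipped)) attr(img, "skipped") <- skipped
  img
}

#' Export an image matrix as PNG or text PGM
#'
#' Intensities are normalised to [0, 1] at export time (a constant image
#' maps to 0).
#'
#' @param image numeric matrix.
#' @param path output file; `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  rng <- range(image)
  norm <- if (diff(rng) > 0) (image - rng[1L]) / diff(rng) else image * 0
  if (grepl("\\.png$", path)) {
    png::writePNG(norm, path)
  } else {
    vals <- round(norm * 255)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)), "255"), con)
    utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
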