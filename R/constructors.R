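#' @include AllClasses.R
NULL

#' Construct a VoxelVolume
#'
#' Values outside the 12-bit scanner range `[-1024, 3071]` HU are clamped on
#' ingest (scanners provide exactly this range; clamping rather than
#' rejecting mirrors that convention).
#'
#' @param data numeric 3D array, dimension order (slice, row, column).
#' @param spacing numeric(3), (dz, dy, dx) in mm.
#' @param origin numeric(3), (z, y, x) in mm. Default zero.
#' @param bits intended storage depth, informational. Default 12.
#' @return a [VoxelVolume-class] object.
#' @examples
#' v <- voxelVolume(array(0, c(4, 8, 8)), spacing = c(2, 1, 1))
#' dims(v)
#' @export
voxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        bits = 12L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    ctsimStop("invalidParameter", "data must be a 3D array (slice, row, column)")
  storage.mode(data) <- "double"
  data[] <- pmin(pmax(data, .HU_MIN), .HU_MAX)
  new("VoxelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), bits = as.integer(bits))
}

#' Construct a BinaryMask
#'
#' @param data array (2D or 3D) coercible to 0/1 (logical accepted).
#' @param spacing numeric, mm spacing matching dimensionality
#'   ((dy, dx) for 2D, (dz, dy, dx) for 3D).
#' @param origin numeric, mm origin matching dimensionality. Default zero.
#' @return a [BinaryMask-class] object.
#' @export
binaryMask <- function(data, spacing, origin = NULL) {
  if (is.logical(data)) {
    d <- dim(data)
    data <- array(as.integer(data), d)
  }
  storage.mode(data) <- "integer"
  if (is.null(origin)) origin <- rep(0, length(dim(data)))
  new("BinaryMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a Contour
#'
#' @param points n x 2 numeric matrix of (y, x) points in mm.
#' @param slice slice index the contour belongs to (NA allowed).
#' @param closed logical, closed polygon? Default TRUE.
#' @return a [Contour-class] object.
#' @export
contour2D <- function(points, slice = NA_integer_, closed = TRUE) {
  points <- as.matrix(points)
  colnames(points) <- c("y", "x")
  new("Contour", points = points, slice = as.integer(slice),
      closed = isTRUE(closed))
}

#' Construct a ContourSet
#'
#' @param contours list of [Contour] objects (one slice each).
#' @param structure structure name.
#' @param sliceSpacing inter-slice spacing in mm.
#' @return a [ContourSet-class] object.
#' @export
contourSet <- function(contours, structure = "structure", sliceSpacing = 1) {
  sl <- vapply(contours, function(cc) cc@slice, integer(1))
  contours <- contours[order(sl)]
  names(contours) <- as.character(sort(sl))
  new("ContourSet", structure = structure, contours = contours,
      sliceSpacing = as.numeric(sliceSpacing))
}

#' Construct a PhantomSpec
#'
#' Defaults describe the two built-in phantoms.  `cubic_spheres` is the
#' verification phantom: a 120 mm cube of water-equivalent material holding a
#' regular grid of 2 mm spheres, scanned at 1 mm slice thickness into 120
#' slices of 512 x 512 pixels.  `thorax` is a ground-truth thorax: an
#' elliptic soft-tissue body on an air background with two ellipsoidal
#' air-valued lungs and a bone-valued spine cylinder.
#'
#' @param kind "cubic_spheres" or "thorax".
#' @param extent world extent (z, y, x) mm. Defaults: cube 120^3; thorax
#'   256 x 384 x 384.
#' @param sliceThickness dz mm (default 1 for the cube, 2 for the thorax).
#' @param matrixSize in-plane (rows, cols) (default 512^2 cube, 256^2 thorax).
#' @param sphereDiameter,spherePitch sphere geometry, mm (cube only;
#'   pitch defaults to 10 mm centre-to-centre).
#' @param tissueHU named HU levels. Cube: background 0 (water), sphere 1000.
#'   Thorax: air -1000, lung -800, soft 40, bone 700.
#' @param noiseSD additive Gaussian HU noise (default 0, off).
#' @param seed RNG seed used when noiseSD > 0.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(kind = c("cubic_spheres", "thorax"),
                        extent = NULL, sliceThickness = NULL,
                        matrixSize = NULL, sphereDiameter = 2,
                        spherePitch = 10, tissueHU = NULL,
                        noiseSD = 0, seed = 0L) {
  kind <- match.arg(kind)
  if (kind == "cubic_spheres") {
    if (is.null(extent)) extent <- c(120, 120, 120)
    if (is.null(sliceThickness)) sliceThickness <- 1
    if (is.null(matrixSize)) matrixSize <- c(512L, 512L)
    if (is.null(tissueHU)) tissueHU <- c(background = 0, sphere = 1000)
  } else {
    if (is.null(extent)) extent <- c(256, 384, 384)
    if (is.null(sliceThickness)) sliceThickness <- 2
    if (is.null(matrixSize)) matrixSize <- c(256L, 256L)
    if (is.null(tissueHU))
      tissueHU <- c(air = -1000, lung = -800, soft = 40, bone = 700)
  }
  new("PhantomSpec", kind = kind, extent = as.numeric(extent),
      sliceThickness = as.numeric(sliceThickness),
      matrixSize = as.integer(matrixSize),
      sphereDiameter = as.numeric(sphereDiameter),
      spherePitch = as.numeric(spherePitch),
      tissueHU = tissueHU, noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' Construct a SeedPoint
#'
#' @param position (slice, row, col) voxel index, 1-based.
#' @param mode seed handling hint: "auto" (decide from the mask), "outside"
#'   or "inside".
#' @return a [SeedPoint-class] object.
#' @export
seedPoint <- function(position, mode = c("auto", "outside", "inside")) {
  new("SeedPoint", position = as.integer(position), mode = match.arg(mode))
}

#' Construct SegmentationParams
#'
#' @param huWindow (low, high) HU window; default the constant 20–70 HU
#'   soft-tissue window.
#' @param minRegionAreaCm2 small-region suppression threshold, cm^2
#'   (default 6).
#' @param rgDelta region-growing grey tolerance, HU (default 50).
#' @param connectivity in-plane connectivity, 4 or 8 (default 8).
#' @param smoothSize odd in-plane majority-smoothing box (default 3; 1 = off).
#' @param decimatePercent contour point removal percentage (default 0).
#' @return a [SegmentationParams-class] object.
#' @export
segmentationParams <- function(huWindow = c(20, 70), minRegionAreaCm2 = 6,
                               rgDelta = 50, connectivity = 8L,
                               smoothSize = 3L, decimatePercent = 0) {
  new("SegmentationParams", huWindow = as.numeric(huWindow),
      minRegionAreaCm2 = as.numeric(minRegionAreaCm2),
      rgDelta = as.numeric(rgDelta),
      connectivity = as.integer(connectivity),
      smoothSize = as.integer(smoothSize),
      decimatePercent = as.numeric(decimatePercent))
}

#' Construct a Camera
#'
#' @param mode "parallel" or "perspective".
#' @param direction view direction (z, y, x); normalised internally.
#' @param center look-at point / image-plane centre (z, y, x) mm.
#' @param imageSize (rows, cols) pixels.
#' @param pixelPitch pixel size on the image plane, mm.
#' @param up approximate up vector (default +y unless parallel to direction,
#'   then +z).
#' @param source ray source for perspective mode (z, y, x) mm.
#' @return a [Camera-class] object.
#' @export
camera <- function(mode = c("parallel", "perspective"),
                   direction = c(1, 0, 0), center = c(0, 0, 0),
                   imageSize = c(64L, 64L), pixelPitch = 1,
                   up = NULL, source = c(NA_real_, NA_real_, NA_real_)) {
  mode <- match.arg(mode)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) ctsimStop("invalidParameter", "direction must be non-zero")
  direction <- direction / nrm
  if (is.null(up)) {
    up <- c(0, 1, 0)
    if (abs(sum(up * direction)) > 0.99) up <- c(1, 0, 0)
  }
  new("Camera", mode = mode, direction = direction, up = as.numeric(up),
      center = as.numeric(center), source = as.numeric(source),
      imageSize = as.integer(imageSize), pixelPitch = as.numeric(pixelPitch))
}

#' Construct a TransferFunction
#'
#' @param hu increasing HU breakpoints.
#' @param attenuation K values (1/mm) for radiograph rendering.
#' @param shade shading intensities C for semi-transparent rendering.
#' @param opacity alpha values in [0, 1] for semi-transparent rendering.
#' @param isovalue HU level for isosurface rendering.
#' @return a [TransferFunction-class] object.
#' @export
transferFunction <- function(hu, attenuation = numeric(), shade = numeric(),
                             opacity = numeric(), isovalue = NA_real_) {
  new("TransferFunction", hu = as.numeric(hu),
      attenuation = as.numeric(attenuation), shade = as.numeric(shade),
      opacity = as.numeric(opacity), isovalue = as.numeric(isovalue))
}

#' Construct a BeamPolygon
#'
#' @param vertices n x 3 matrix of (z, y, x) mm vertices; must be planar.
#' @param color polygon display value (default 1).
#' @param role "beam" or "block".
#' @return a [BeamPolygon-class] object.
#' @export
beamPolygon <- function(vertices, color = 1, role = c("beam", "block")) {
  new("BeamPolygon", vertices = as.matrix(vertices), color = as.numeric(color),
      role = match.arg(role))
}
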