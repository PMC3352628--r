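#' @import methods
NULL

## Hounsfield storage range of a 12-bit medical scanner: 4096 integer values.
.HU_MIN <- -1024L
.HU_MAX <- 3071L

#' VoxelVolume: a 3D grid of Hounsfield values with anisotropic spacing
#'
#' The central data object of the package: an axial stack of CT slices stored
#' as a 3D array in `(slice, row, column)` order.  `spacing` and `origin` are
#' `(dz, dy, dx)` / `(z, y, x)` in millimetres.  A voxel's world coordinate is
#' its centre: voxel `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 0.5) * spacing`, so the world extent along an axis
#' with `n` voxels is `n * spacing` (half-open voxel cells).  Values are
#' clamped on ingest to the 12-bit scanner range `[-1024, 3071]` HU.
#'
#' @slot data numeric 3D array, dimension order (slice, row, column).
#' @slot spacing numeric(3), voxel spacing (dz, dy, dx) in mm, all > 0.
#' @slot origin numeric(3), world position (z, y, x) in mm of the corner of
#'   the first voxel cell.
#' @slot bits integer(1), intended storage depth (informational, default 12).
#'
#' @seealso [voxelVolume()], [loadVolume()], [writeVolume()]
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 bits = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), bits = 12L))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3D array (slice, row, column)")
  if (d[1L] < 1L || d[2L] < 2L || d[3L] < 2L)
    return("volume needs >= 1 slice, >= 2 rows and >= 2 columns")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three positive finite values (dz, dy, dx)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values (z, y, x)")
  rng <- range(object@data)
  if (rng[1L] < .HU_MIN || rng[2L] > .HU_MAX)
    return(sprintf("HU values outside [%d, %d]; construct with voxelVolume() to clamp",
                   .HU_MIN, .HU_MAX))
  TRUE
})

#' BinaryMask: object/background labelling of a volume or a single slice
#'
#' Values are strictly 0 (background) or 1 (object).  For a 3D mask the grid
#' is congruent with its source [VoxelVolume]; 2D masks label one slice.
#' Spacing and origin follow the source volume conventions.
#'
#' @slot data integer/numeric array (2D or 3D) with values in {0, 1}.
#' @slot spacing numeric, (dy, dx) for 2D or (dz, dy, dx) for 3D, in mm.
#' @slot origin numeric, matching length of `spacing`, in mm.
#'
#' @seealso [binaryMask()], [thresholdMask()]
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("BinaryMask", function(object) {
  d <- dim(object@data)
  if (!length(d) %in% c(2L, 3L))
    return("mask data must be a 2D or 3D array")
  if (length(object@spacing) != length(d))
    return("spacing length must match mask dimensionality")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  v <- object@data
  if (any(v != 0 & v != 1)) return("mask values must be 0 or 1")
  TRUE
})

#' Contour: an ordered point list on one slice
#'
#' Points are `(y, x)` world coordinates in millimetres, ordered along the
#' boundary.  A closed contour implicitly joins the last point back to the
#' first; the closing point is not duplicated in `points`.  Consecutive
#' duplicate points are forbidden.  Raster boundary traces of very small
#' regions may legitimately contain fewer than 3 points; such degenerate
#' closed contours have zero area.
#'
#' @slot slice integer(1), slice index the contour lives on (1-based;
#'   `NA` for slice-independent geometry such as interpolated contours).
#' @slot points numeric matrix, n x 2, columns (y, x) in mm.
#' @slot closed logical(1).
#'
#' @seealso [contour2D()], [contourArea()], [contourPeriphery()]
#' @export
setClass("Contour",
  representation(slice = "integer", points = "matrix", closed = "logical"),
  prototype(slice = NA_integer_, closed = TRUE))

setValidity("Contour", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L) return("points must be an n x 2 numeric matrix")
  if (nrow(p) < 1L) return("contour needs at least one point")
  if (any(!is.finite(p))) return("contour points must be finite")
  if (nrow(p) >= 2L) {
    dup <- rowSums(abs(diff(p))) == 0
    if (any(dup)) return("consecutive duplicate points are forbidden")
    if (object@closed && nrow(p) >= 2L &&
        all(abs(p[1L, ] - p[nrow(p), ]) < 1e-12) && nrow(p) > 1L)
      return("closed contours must not repeat the first point at the end")
  }
  TRUE
})

#' ContourSet: one structure's contours across slices
#'
#' At most one contour per slice; contours are kept sorted by slice index.
#'
#' @slot structure character(1), structure name (e.g. "left_lung").
#' @slot contours list of [Contour], names are slice indices.
#' @slot sliceSpacing numeric(1), inter-slice spacing dz in mm.
#'
#' @export
setClass("ContourSet",
  representation(structure = "character", contours = "list",
                 sliceSpacing = "numeric"))

setValidity("ContourSet", function(object) {
  if (length(object@sliceSpacing) != 1L || object@sliceSpacing <= 0)
    return("sliceSpacing must be a single positive value")
  sl <- vapply(object@contours, function(cc) cc@slice, integer(1))
  if (anyDuplicated(sl)) return("at most one contour per slice")
  if (is.unsorted(sl)) return("contours must be sorted by slice index")
  if (!all(vapply(object@contours, is, logical(1), "Contour")))
    return("contours must all be Contour objects")
  TRUE
})

#' PhantomSpec: parametric description of a synthetic test volume
#'
#' @slot kind character(1), "cubic_spheres" or "thorax".
#' @slot extent numeric(3), world extent (z, y, x) in mm.
#' @slot sliceThickness numeric(1), dz in mm.
#' @slot matrixSize integer(2), in-plane (rows, cols).
#' @slot sphereDiameter,spherePitch numeric(1), mm (cubic_spheres only).
#' @slot tissueHU named numeric, HU levels; thorax uses lung/soft/bone/air,
#'   cubic_spheres uses background/sphere.
#' @slot noiseSD numeric(1), additive Gaussian HU noise sd (0 = off).
#' @slot seed integer(1), RNG seed for the noise.
#'
#' @seealso [phantomSpec()], [generateCubicPhantom()], [generateThorax()]
#' @export
setClass("PhantomSpec",
  representation(kind = "character", extent = "numeric",
                 sliceThickness = "numeric", matrixSize = "integer",
                 sphereDiameter = "numeric", spherePitch = "numeric",
                 tissueHU = "numeric", noiseSD = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!object@kind %in% c("cubic_spheres", "thorax"))
    return("kind must be 'cubic_spheres' or 'thorax'")
  if (length(object@extent) != 3L || any(object@extent <= 0))
    return("extent must be three positive values (z, y, x) in mm")
  if (object@sliceThickness <= 0) return("sliceThickness must be > 0")
  if (length(object@matrixSize) != 2L || any(object@matrixSize < 2L))
    return("matrixSize must be two integers >= 2")
  if (object@kind == "cubic_spheres") {
    if (object@sphereDiameter <= 0 || object@spherePitch <= 0)
      return("sphereDiameter and spherePitch must be > 0")
    if (object@sphereDiameter >= object@spherePitch)
      return("sphereDiameter must be smaller than spherePitch")
  }
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' GroundTruth: named ground-truth masks accompanying a generated phantom
#'
#' For the thorax phantom the masks are `left_lung`, `right_lung`, `spine`
#' and `body`; `body` is the external patient outline and therefore contains
#' the lungs and spine, while the organ masks are pairwise disjoint.  The
#' cubic phantom carries a single `spheres` mask.
#'
#' @slot masks named list of [BinaryMask], each congruent with the volume.
#' @export
setClass("GroundTruth", representation(masks = "list"))

setValidity("GroundTruth", function(object) {
  if (is.null(names(object@masks)) || any(names(object@masks) == ""))
    return("masks must be a named list")
  if (!all(vapply(object@masks, is, logical(1), "BinaryMask")))
    return("masks must all be BinaryMask objects")
  TRUE
})

#' SeedPoint: a user-selected starting point for segmentation
#'
#' @slot position integer(3), (slice, row, col) voxel index, 1-based.
#' @slot mode character(1), "auto", "outside" or "inside" — how the seed
#'   relates to the structure of interest.
#' @seealso [seedPoint()], [segmentStructure()]
#' @export
setClass("SeedPoint",
  representation(position = "integer", mode = "character"),
  prototype(mode = "auto"))

setValidity("SeedPoint", function(object) {
  if (length(object@position) != 3L || any(object@position < 1L))
    return("position must be three positive indices (slice, row, col)")
  if (!object@mode %in% c("auto", "outside", "inside"))
    return("mode must be 'auto', 'outside' or 'inside'")
  TRUE
})

#' SegmentationParams: tunable parameters of the segmentation pipeline
#'
#' @slot huWindow numeric(2), (low, high) HU; voxels with low <= HU <= high
#'   are object.  The constant 20–70 HU window is the historical soft-tissue
#'   default; organ-appropriate windows (e.g. around -800 HU for lung) are
#'   set per structure.
#' @slot minRegionAreaCm2 numeric(1), in-plane regions with area <= this are
#'   suppressed before tracing (default 6 cm^2).
#' @slot rgDelta numeric(1), grey-level tolerance for region growing.
#' @slot connectivity integer(1), in-plane connectivity 4 or 8 (3D growing is
#'   always 6-connected).
#' @slot smoothSize integer(1), odd box size for in-plane majority smoothing
#'   of the thresholded mask (1 = off).
#' @slot decimatePercent numeric(1), contour point removal percentage k
#'   applied to emitted contours (0 = keep all points).
#' @seealso [segmentationParams()], [segmentStructure()]
#' @export
setClass("SegmentationParams",
  representation(huWindow = "numeric", minRegionAreaCm2 = "numeric",
                 rgDelta = "numeric", connectivity = "integer",
                 smoothSize = "integer", decimatePercent = "numeric"))

setValidity("SegmentationParams", function(object) {
  if (length(object@huWindow) != 2L || object@huWindow[1L] >= object@huWindow[2L])
    return("huWindow must be (low, high) with low < high")
  if (object@minRegionAreaCm2 <= 0) return("minRegionAreaCm2 must be > 0")
  if (object@rgDelta < 0) return("rgDelta must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  if (object@smoothSize < 1L || object@smoothSize %% 2L == 0L)
    return("smoothSize must be odd and >= 1")
  if (object@decimatePercent < 0 || object@decimatePercent >= 100)
    return("decimatePercent must be in [0, 100)")
  TRUE
})

#' SegmentationResult: contours plus filled mask from [segmentStructure()]
#'
#' @slot contours [ContourSet] with one traced contour per segmented slice.
#' @slot mask [BinaryMask], the filled 3D mask (rasterised contours).
#' @slot warnings character, diagnostics (e.g. structure vanishing mid-stack).
#' @export
setClass("SegmentationResult",
  representation(contours = "ContourSet", mask = "BinaryMask",
                 warnings = "character"))

#' Camera: viewing geometry for volume rendering
#'
#' All positions/directions are world-millimetre `(z, y, x)` vectors.  For a
#' parallel camera rays share `direction` and originate on the image plane
#' through `center`.  For a perspective camera (Beam's Eye View style) rays
#' start at `source` and pass through the pixel grid on the plane through
#' `center` perpendicular to `direction`.  Depth (the Z-buffer value) is the
#' distance along the ray from its origin plane and increases away from the
#' viewer.
#'
#' @slot mode character(1), "parallel" or "perspective".
#' @slot direction numeric(3), unit view direction (viewer towards scene).
#' @slot up numeric(3), approximate up vector fixing the image-plane roll.
#' @slot center numeric(3), look-at point / image plane centre, mm.
#' @slot source numeric(3), ray source for perspective mode (NA otherwise).
#' @slot imageSize integer(2), image (rows, cols) in pixels.
#' @slot pixelPitch numeric(1), pixel size on the image plane, mm.
#' @seealso [camera()], [renderDRR()]
#' @export
setClass("Camera",
  representation(mode = "character", direction = "numeric", up = "numeric",
                 center = "numeric", source = "numeric",
                 imageSize = "integer", pixelPitch = "numeric"))

setValidity("Camera", function(object) {
  if (!object@mode %in% c("parallel", "perspective"))
    return("mode must be 'parallel' or 'perspective'")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    return("imageSize must be two positive integers (rows, cols)")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@mode == "perspective" && any(!is.finite(object@source)))
    return("perspective mode requires a finite source position")
  TRUE
})

#' TransferFunction: HU-to-optical-property mapping for rendering
#'
#' Piecewise-linear breakpoints over HU.  `attenuation` (K >= 0, 1/mm) feeds
#' the radiograph line integral; `shade` and `opacity` (alpha in [0, 1]) feed
#' semi-transparent accumulation; `isovalue` selects the surface for
#' isosurface renders.  Evaluation clamps outside the breakpoint range.
#'
#' @slot hu numeric, increasing HU breakpoints.
#' @slot attenuation numeric, K at each breakpoint (>= 0).
#' @slot shade numeric, shading intensity C at each breakpoint.
#' @slot opacity numeric, alpha at each breakpoint, in [0, 1].
#' @slot isovalue numeric(1), HU isosurface level (NA if unused).
#' @seealso [transferFunction()]
#' @export
setClass("TransferFunction",
  representation(hu = "numeric", attenuation = "numeric", shade = "numeric",
                 opacity = "numeric", isovalue = "numeric"),
  prototype(isovalue = NA_real_))

setValidity("TransferFunction", function(object) {
  if (length(object@hu) < 1L || is.unsorted(object@hu, strictly = TRUE))
    return("hu breakpoints must be strictly increasing")
  for (nm in c("attenuation", "shade", "opacity")) {
    v <- slot(object, nm)
    if (length(v) && length(v) != length(object@hu))
      return(sprintf("%s must have one value per hu breakpoint", nm))
  }
  if (length(object@attenuation) && any(object@attenuation < 0))
    return("attenuation must be >= 0")
  if (length(object@opacity) && (any(object@opacity < 0) || any(object@opacity > 1)))
    return("opacity must be within [0, 1]")
  TRUE
})

#' RenderResult: intensity image plus first-surface depth buffer
#'
#' @slot image numeric matrix (rows x cols).
#' @slot zbuffer numeric matrix congruent with `image`; depth along the ray
#'   of the first rendered surface, `far` where no surface was met.
#' @slot far numeric(1), the far-plane depth value.
#' @export
setClass("RenderResult",
  representation(image = "matrix", zbuffer = "matrix", far = "numeric"))

setValidity("RenderResult", function(object) {
  if (!identical(dim(object@image), dim(object@zbuffer)))
    return("image and zbuffer must be congruent")
  TRUE
})

#' BeamPolygon: a planar beam or block polygon in volume coordinates
#'
#' @slot vertices numeric matrix n x 3, world (z, y, x) mm; n >= 3, planar.
#' @slot color numeric(1), polygon display value.
#' @slot role character(1), "beam" or "block".
#' @seealso [beamPolygon()], [compositePolygons()]
#' @export
setClass("BeamPolygon",
  representation(vertices = "matrix", color = "numeric", role = "character"),
  prototype(color = 1, role = "beam"))

setValidity("BeamPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 3L || nrow(v) < 3L)
    return("vertices must be an n x 3 matrix with n >= 3")
  if (!object@role %in% c("beam", "block"))
    return("role must be 'beam' or 'block'")
  n <- .polyNormal(v)
  if (sqrt(sum(n^2)) < 1e-12) return("polygon is degenerate")
  n <- n / sqrt(sum(n^2))
  d <- abs((v - matrix(v[1L, ], nrow(v), 3L, byrow = TRUE)) %*% n)
  if (max(d) > 1e-6 * max(1, max(abs(v))))
    return("polygon vertices are not coplanar")
  TRUE
})
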