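#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelData", "BinaryMask", function(x) x@data)
#' @rdname accessors
setMethod("spacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "VoxelVolume", function(x) x@origin)
#' @rdname accessors
setMethod("origin", "BinaryMask", function(x) x@origin)
#' @rdname accessors
setMethod("dims", "VoxelVolume", function(x) dim(x@data))
#' @rdname accessors
setMethod("dims", "BinaryMask", function(x) dim(x@data))
#' @rdname accessors
setMethod("nSlices", "VoxelVolume", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nSlices", "BinaryMask",
          function(x) if (length(dim(x@data)) == 3L) dim(x@data)[1L] else 1L)
#' @rdname accessors
setMethod("contourPoints", "Contour", function(x) x@points)
#' @rdname accessors
setMethod("isClosed", "Contour", function(x) x@closed)
#' @rdname accessors
setMethod("sliceIndex", "Contour", function(x) x@slice)
#' @rdname accessors
setMethod("structureName", "ContourSet", function(x) x@structure)
#' @rdname accessors
setMethod("groundTruthMasks", "GroundTruth", function(x) x@masks)
#' @rdname accessors
setMethod("renderImage", "RenderResult", function(x) x@image)
#' @rdname accessors
setMethod("zBuffer", "RenderResult", function(x) x@zbuffer)
#' @rdname accessors
setMethod("structureContours", "SegmentationResult", function(x) x@contours)
#' @rdname accessors
setMethod("structureMask", "SegmentationResult", function(x) x@mask)

#' Length of a ContourSet is its number of contours
#' @param x a [ContourSet].
#' @export
setMethod("length", "ContourSet", function(x) length(x@contours))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz, dy, dx): %.4g x %.4g x %.4g mm\n",
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin  (z, y, x):    %.4g, %.4g, %.4g mm\n",
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  HU range: [%.4g, %.4g], %d-bit storage\n",
              min(object@data), max(object@data), object@bits))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask: %s, %d object voxels (%.2f%%)\n",
              paste(d, collapse = " x "), sum(object@data != 0),
              100 * mean(object@data != 0)))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour: %d points, %s, slice %s\n", nrow(object@points),
              if (object@closed) "closed" else "open",
              ifelse(is.na(object@slice), "<none>", object@slice)))
})

setMethod("show", "ContourSet", function(object) {
  sl <- vapply(object@contours, function(cc) cc@slice, integer(1))
  cat(sprintf("ContourSet '%s': %d contours%s, slice spacing %.4g mm\n",
              object@structure, length(object@contours),
              if (length(sl)) sprintf(" on slices %d..%d", min(sl), max(sl)) else "",
              object@sliceSpacing))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': extent %s mm, slices %.4g mm thick, matrix %s\n",
              object@kind, paste(object@extent, collapse = " x "),
              object@sliceThickness, paste(object@matrixSize, collapse = " x ")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %s\n", paste(names(object@masks), collapse = ", ")))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult '%s': %d contours, %d mask voxels\n",
              object@contours@structure, length(object@contours@contours),
              sum(object@mask@data != 0)))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "RenderResult", function(object) {
  d <- dim(object@image)
  cat(sprintf("RenderResult: %d x %d image, intensity [%.4g, %.4g], far = %.4g\n",
              d[1], d[2], min(object@image), max(object@image), object@far))
})

setMethod("show", "Camera", function(object) {
  cat(sprintf("Camera (%s): %d x %d px @ %.4g mm, direction (%.3g, %.3g, %.3g)\n",
              object@mode, object@imageSize[1], object@imageSize[2],
              object@pixelPitch, object@direction[1], object@direction[2],
              object@direction[3]))
})
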