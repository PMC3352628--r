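#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' `voxelData()` returns the raw array of a [VoxelVolume] or [BinaryMask];
#' `spacing()` and `origin()` return the mm geometry; `dims()` the grid
#' dimensions; `nSlices()` the number of axial slices.
#'
#' @param x a ctsim data object.
#' @return the slot contents (see details per class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("dims", function(x) standardGeneric("dims"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))

#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))

#' @rdname accessors
#' @export
setGeneric("sliceIndex", function(x) standardGeneric("sliceIndex"))

#' @rdname accessors
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))

#' @rdname accessors
#' @export
setGeneric("groundTruthMasks", function(x) standardGeneric("groundTruthMasks"))

#' @rdname accessors
#' @export
setGeneric("renderImage", function(x) standardGeneric("renderImage"))

#' @rdname accessors
#' @export
setGeneric("zBuffer", function(x) standardGeneric("zBuffer"))

#' @rdname accessors
#' @export
setGeneric("structureContours", function(x) standardGeneric("structureContours"))

#' @rdname accessors
#' @export
setGeneric("structureMask", function(x) standardGeneric("structureMask"))
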