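#' Read a CT volume from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`raw_json`}{this package's plain fixture format: `<path>.json`
#'     sidecar (shape, spacing, origin, dtype) plus `<path>.raw` holding
#'     little-endian int16 voxels in (slice, row, column) C order.}
#'   \item{`nifti`}{NIfTI-1 single file (`.nii`), via \pkg{oro.nifti};
#'     spacing from `pixdim`, origin from the q-form offsets.}
#'   \item{`dicom_series`}{a directory of single-frame CT DICOM files
#'     (explicit or implicit VR little endian); slices are sorted by patient
#'     z position and the inter-slice spacing must be uniform.}
#' }
#' HU values are clamped to `[-1024, 3071]` on ingest; slices are ordered
#' ascending along the patient axis.
#'
#' @param path file (nifti), path prefix (raw_json) or directory
#'   (dicom_series).
#' @param format one of `"raw_json"`, `"nifti"`, `"dicom_series"`; guessed
#'   from `path` when missing (directory -> DICOM, `.nii` -> NIfTI,
#'   otherwise raw_json).
#' @return a [VoxelVolume-class].
#' @seealso [writeVolume()]
#' @export
loadVolume <- function(path, format = c("auto", "raw_json", "nifti",
                                        "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series"
      else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else "raw_json"
  }
  switch(format,
    raw_json = .loadRawJson(path),
    nifti = .loadNifti(path),
    dicom_series = readDicomSeries(path))
}

#' Write a CT volume (or mask) to disk
#'
#' Integer HU data round-trips bit-exactly through both writable formats;
#' spacing and origin are preserved.  Non-integer data are rounded to the
#' nearest HU in `raw_json` (int16 storage).
#'
#' @param volume a [VoxelVolume-class] or [BinaryMask-class] (3D).
#' @param path destination: path prefix for `raw_json` (writes `.json` +
#'   `.raw`), file name for `nifti` (`.nii` appended if absent).
#' @param format `"raw_json"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, format = c("raw_json", "nifti")) {
  format <- match.arg(format)
  mask <- is(volume, "BinaryMask")
  if (mask && length(dim(volume@data)) != 3L)
    ctsimStop("invalidParameter", "only 3D masks can be written as volumes")
  if (!mask && !is(volume, "VoxelVolume"))
    ctsimStop("invalidParameter", "volume must be a VoxelVolume or 3D BinaryMask")
  if (!dir.exists(dirname(path)))
    ctsimStop("ioError", sprintf("destination directory does not exist: %s",
                                 dirname(path)))
  if (format == "raw_json") .writeRawJson(volume, path, mask) else
    .writeNifti(volume, path)
  invisible(path)
}

.loadRawJson <- function(path) {
  jsonPath <- paste0(path, ".json"); rawPath <- paste0(path, ".raw")
  if (!file.exists(jsonPath) || !file.exists(rawPath))
    ctsimStop("ioError", sprintf("missing raw_json pair: %s{.json,.raw}", path))
  meta <- tryCatch(jsonlite::read_json(jsonPath, simplifyVector = TRUE),
                   error = function(e)
                     ctsimStop("corruptFile", sprintf("unparseable JSON sidecar: %s",
                                                      conditionMessage(e))))
  need <- c("shape", "spacing", "origin")
  if (!all(need %in% names(meta)))
    ctsimStop("corruptFile", "raw_json sidecar lacks shape/spacing/origin")
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(rawPath, "rb"); on.exit(close(con))
  vals <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) != n)
    ctsimStop("corruptFile", sprintf("raw block holds %d voxels, sidecar says %d",
                                     length(vals), n))
  ## C order (slice, row, column): column index fastest.
  arr <- aperm(array(as.numeric(vals), rev(shape)), 3:1)
  if (identical(meta$kind, "mask"))
    return(binaryMask(arr, spacing = as.numeric(meta$spacing),
                      origin = as.numeric(meta$origin)))
  voxelVolume(arr, spacing = as.numeric(meta$spacing),
              origin = as.numeric(meta$origin),
              bits = if (!is.null(meta$bits)) meta$bits else 12L)
}

.writeRawJson <- function(volume, path, mask) {
  shape <- dim(volume@data)
  meta <- list(shape = shape, spacing = volume@spacing, origin = volume@origin,
               dtype = "int16", byte_order = "little",
               kind = if (mask) "mask" else "volume")
  if (!mask) meta$bits <- volume@bits
  ok <- tryCatch({
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    con <- file(paste0(path, ".raw"), "wb")
    on.exit(close(con))
    vals <- as.integer(round(aperm(volume@data, 3:1)))
    writeBin(vals, con, size = 2L, endian = "little")
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) ctsimStop("ioError", sprintf("write failed: %s", ok))
}

.loadNifti <- function(path) {
  if (!file.exists(path))
    ctsimStop("ioError", sprintf("no such file: %s", path))
  img <- tryCatch(oro.nifti::readNIfTI(path, reorient = FALSE),
                  error = function(e)
                    ctsimStop("corruptFile", sprintf("NIfTI read failed: %s",
                                                     conditionMessage(e))))
  a <- img@.Data                    # (x, y, z)
  if (length(dim(a)) != 3L)
    ctsimStop("unsupportedFormat", "only 3D NIfTI volumes are supported")
  sp <- oro.nifti::pixdim(img)[2:4] # (dx, dy, dz)
  or <- c(img@qoffset_z, img@qoffset_y, img@qoffset_x)
  voxelVolume(aperm(a, 3:1), spacing = rev(sp), origin = or)
}

.writeNifti <- function(volume, path) {
  path <- sub("\\.nii$", "", path)
  a <- round(aperm(volume@data, 3:1))   # back to (x, y, z)
  storage.mode(a) <- "integer"
  img <- oro.nifti::nifti(a, datatype = 4)  # int16
  oro.nifti::pixdim(img)[1:4] <- c(1, rev(volume@spacing))
  img@qform_code <- 1
  img@qoffset_x <- volume@origin[3L]
  img@qoffset_y <- volume@origin[2L]
  img@qoffset_z <- volume@origin[1L]
  ok <- tryCatch({oro.nifti::writeNIfTI(img, path, gzipped = FALSE); TRUE},
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) ctsimStop("ioError", sprintf("NIfTI write failed: %s", ok))
}
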