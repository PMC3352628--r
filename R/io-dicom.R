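## Minimal DICOM series reader: single-frame CT slices, explicit or implicit
## VR little endian, uncompressed 16-bit pixel data.  Written in-package
## because no installed R package parses DICOM; scope is deliberately the
## subset a CT scanner export uses.

.dicomTags <- list(
  rows = c(0x0028L, 0x0010L), cols = c(0x0028L, 0x0011L),
  pixelSpacing = c(0x0028L, 0x0030L), sliceThickness = c(0x0018L, 0x0050L),
  position = c(0x0020L, 0x0032L), instance = c(0x0020L, 0x0013L),
  bitsAllocated = c(0x0028L, 0x0100L), pixelRepresentation = c(0x0028L, 0x0103L),
  rescaleIntercept = c(0x0028L, 0x1052L), rescaleSlope = c(0x0028L, 0x1053L),
  pixelData = c(0x7FE0L, 0x0010L))

.EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.IMPLICIT_LE <- "1.2.840.10008.1.2"

#' Read a directory of DICOM CT slices as a volume
#'
#' Parses single-frame little-endian DICOM files (explicit or implicit VR),
#' applies the rescale slope/intercept to obtain HU, sorts slices by the
#' patient z position and checks that the inter-slice spacing is uniform.
#'
#' @param dir directory containing one `.dcm`/extension-less file per slice.
#' @return a [VoxelVolume-class].
#' @seealso [loadVolume()]
#' @export
readDicomSeries <- function(dir) {
  if (!dir.exists(dir)) ctsimStop("ioError", sprintf("no such directory: %s", dir))
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) ctsimStop("ioError", sprintf("no files in %s", dir))
  slices <- lapply(files, .readDicomFile)
  z <- vapply(slices, function(s) s$position[3L], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dims <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    ctsimStop("corruptFile", "slices disagree on matrix size")
  if (length(z) > 1L) {
    dz <- diff(z)
    if (any(dz <= 0))
      ctsimStop("corruptFile", "duplicate slice positions in series")
    if (max(dz) - min(dz) > 1e-4 * max(dz))
      ctsimStop("inconsistentSpacing",
                sprintf("non-uniform slice spacing: %.6g..%.6g mm",
                        min(dz), max(dz)))
    dz <- dz[1L]
  } else dz <- slices[[1L]]$sliceThickness
  nr <- dims[1L, 1L]; nc <- dims[2L, 1L]
  data <- array(0, c(length(slices), nr, nc))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]$pixels
  ps <- slices[[1L]]$pixelSpacing   # (row spacing dy, col spacing dx)
  pos <- slices[[1L]]$position      # (x, y, z) of first voxel centre
  or <- c(z[1L] - dz / 2, pos[2L] - ps[1L] / 2, pos[1L] - ps[2L] / 2)
  voxelVolume(data, spacing = c(dz, ps[1L], ps[2L]), origin = or)
}

.readDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  off <- 0L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  else ctsimStop("corruptFile", sprintf("not a DICOM part-10 file: %s", path))

  u16 <- function(i) as.integer(raw[i + 1L]) + 256L * as.integer(raw[i + 2L])
  u32 <- function(i) as.integer(raw[i + 1L]) + 256L * as.integer(raw[i + 2L]) +
    65536 * as.integer(raw[i + 3L]) + 16777216 * as.integer(raw[i + 4L])

  ## ---- file meta group (always explicit VR) ----
  ts <- NULL
  i <- off
  while (i + 8L <= length(raw)) {
    group <- u16(i); elem <- u16(i + 2L)
    if (group != 0x0002L) break
    vr <- rawToChar(raw[(i + 5L):(i + 6L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(i + 8L); vstart <- i + 12L
    } else { len <- u16(i + 6L); vstart <- i + 8L }
    if (group == 0x0002L && elem == 0x0010L)
      ts <- .dicomStr(raw[(vstart + 1L):(vstart + len)])
    i <- vstart + len
  }
  if (is.null(ts))
    ctsimStop("corruptFile", sprintf("missing transfer syntax: %s", path))
  if (!ts %in% c(.EXPLICIT_LE, .IMPLICIT_LE))
    ctsimStop("unsupportedFormat",
              sprintf("unsupported transfer syntax %s (only little-endian uncompressed)", ts))
  explicit <- ts == .EXPLICIT_LE

  got <- list(rescaleIntercept = 0, rescaleSlope = 1, sliceThickness = 1)
  while (i + 8L <= length(raw)) {
    group <- u16(i); elem <- u16(i + 2L)
    if (explicit) {
      vr <- rawToChar(raw[(i + 5L):(i + 6L)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(i + 8L); vstart <- i + 12L
      } else { len <- u16(i + 6L); vstart <- i + 8L }
    } else { vr <- ""; len <- u32(i + 4L); vstart <- i + 8L }
    if (len >= 4294967295 || vr == "SQ")
      ctsimStop("unsupportedFormat",
                "sequences / undefined lengths are not supported")
    val <- raw[(vstart + 1L):(vstart + len)]
    key <- .tagName(group, elem)
    if (!is.null(key)) {
      got[[key]] <- switch(key,
        rows = , cols = , bitsAllocated = , pixelRepresentation =
          if (explicit || len == 2L) u16(vstart) else u32(vstart),
        instance = as.integer(.dicomStr(val)),
        pixelSpacing = , position = as.numeric(
          strsplit(.dicomStr(val), "\\\\")[[1L]]),
        sliceThickness = , rescaleIntercept = , rescaleSlope =
          as.numeric(.dicomStr(val)),
        pixelData = val)
    }
    i <- vstart + len
  }
  for (nm in c("rows", "cols", "position", "pixelSpacing", "pixelData"))
    if (is.null(got[[nm]]))
      ctsimStop("corruptFile", sprintf("missing %s in %s", nm, path))
  if (!is.null(got$bitsAllocated) && got$bitsAllocated != 16L)
    ctsimStop("unsupportedFormat", "only 16-bit pixel data supported")
  signed <- isTRUE(got$pixelRepresentation == 1L)
  px <- readBin(got$pixelData, "integer", n = got$rows * got$cols, size = 2L,
                signed = signed, endian = "little")
  if (length(px) != got$rows * got$cols)
    ctsimStop("corruptFile", sprintf("truncated pixel data in %s", path))
  ## DICOM pixel order: row-major (column index fastest)
  pixels <- matrix(px, nrow = got$rows, ncol = got$cols, byrow = TRUE)
  pixels <- pixels * got$rescaleSlope + got$rescaleIntercept
  got$pixels <- pixels
  got
}

.tagName <- function(group, elem) {
  for (nm in names(.dicomTags)) {
    tg <- .dicomTags[[nm]]
    if (tg[1L] == group && tg[2L] == elem) return(nm)
  }
  NULL
}

.dicomStr <- function(val) {
  s <- rawToChar(val[val != as.raw(0L)])
  sub("\\s+$", "", sub("^\\s+", "", s))
}
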