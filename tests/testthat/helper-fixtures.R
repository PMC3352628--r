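## Shared fixtures, all generated in code at test time.

## Small thorax phantom for fast pipeline tests (1.5 mm pixels, 4 mm
## slices).  The organ geometry scales with the extents, so the small-area
## suppression threshold must be scaled down alongside.
smallThoraxSpec <- function(...) {
  phantomSpec("thorax", extent = c(64, 96, 96), sliceThickness = 4,
              matrixSize = c(64L, 64L), ...)
}

smallParams <- function(huWindow, ...) {
  segmentationParams(huWindow = huWindow, minRegionAreaCm2 = 0.1, ...)
}

## Write a DICOM CT series with pydicom (independent reference writer) plus
## per-slice pixel CSVs for value-level comparison.  `gapSlice` (0-based)
## doubles one inter-slice gap to emulate a missing slice.
writeDicomFixture <- function(dir, nz = 4, nr = 8, nc = 6, gapSlice = -1,
                              implicit = FALSE) {
  script <- file.path(dir, "make_series.py")
  writeLines(c(
    "import sys, csv",
    "import numpy as np",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid",
    sprintf("outdir, nz, nr, nc, gap, implicit = %s", paste0(
      "sys.argv[1], ", "int(sys.argv[2]), int(sys.argv[3]), ",
      "int(sys.argv[4]), int(sys.argv[5]), int(sys.argv[6])")),
    "rng = np.random.default_rng(42)",
    "series = generate_uid()",
    "z = 0.0",
    "for i in range(nz):",
    "    ds = Dataset()",
    "    ds.SOPClassUID = '1.2.840.10008.5.1.4.1.1.2'",
    "    ds.SOPInstanceUID = generate_uid()",
    "    ds.SeriesInstanceUID = series",
    "    ds.Modality = 'CT'",
    "    ds.Rows, ds.Columns = nr, nc",
    "    ds.BitsAllocated, ds.BitsStored, ds.HighBit = 16, 12, 11",
    "    ds.PixelRepresentation = 1",
    "    ds.SamplesPerPixel = 1",
    "    ds.PhotometricInterpretation = 'MONOCHROME2'",
    "    ds.PixelSpacing = ['0.8', '0.6']",
    "    ds.SliceThickness = '2.0'",
    "    ds.InstanceNumber = i + 1",
    "    ds.ImagePositionPatient = ['10.0', '20.0', str(z)]",
    "    ds.ImageOrientationPatient = ['1','0','0','0','1','0']",
    "    ds.RescaleIntercept = '-1024'",
    "    ds.RescaleSlope = '1'",
    "    px = rng.integers(0, 3000, size=(nr, nc), dtype=np.int16)",
    "    ds.PixelData = px.tobytes()",
    "    np.savetxt(f'{outdir}/ref_{i:03d}.csv', px, fmt='%d', delimiter=',')",
    "    meta = FileMetaDataset()",
    "    meta.TransferSyntaxUID = ImplicitVRLittleEndian if implicit else ExplicitVRLittleEndian",
    "    meta.MediaStorageSOPClassUID = ds.SOPClassUID",
    "    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID",
    "    ds.file_meta = meta",
    "    ds.save_as(f'{outdir}/slice_{i:03d}.dcm', enforce_file_format=True)",
    "    z += 2.0 if (gap < 0 or i != gap) else 4.0"), script)
  status <- system2("python", c(script, dir, nz, nr, nc, gapSlice,
                                as.integer(implicit)),
                    stdout = FALSE, stderr = FALSE)
  file.remove(script)
  status == 0
}

readDicomRefSlices <- function(dir) {
  files <- sort(list.files(dir, pattern = "^ref_.*\\.csv$", full.names = TRUE))
  out <- lapply(files, function(f) {
    m <- as.matrix(utils::read.csv(f, header = FALSE))
    dimnames(m) <- NULL
    m
  })
  file.remove(files)
  out
}

regularPolygonContour <- function(nPoints, radius, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = nPoints + 1)[-(nPoints + 1)]
  contour2D(cbind(center[1] + radius * sin(th), center[2] + radius * cos(th)))
}
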