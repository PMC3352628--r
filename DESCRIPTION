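Package: ctsim
Title: CT Volume Segmentation, Contouring and Virtual-Simulation Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for radiotherapy virtual simulation on computed-tomography
    volumes: Hounsfield-unit voxel volumes with DICOM series, NIfTI-1 and
    raw+JSON input/output; synthetic verification phantoms (sphere grid cube,
    thorax) with ground-truth masks; 2D filtering (convolution, box smoothing,
    Sobel edge magnitude, histogram-derived thresholding); semi-automatic
    structure segmentation by Moore boundary tracking with seed relocation,
    seeded region growing and small-region suppression; contour area and
    periphery metrics, point decimation and triangulated inter-slice contour
    interpolation; trilinear resampling to isotropic voxels; and digitally
    reconstructed radiograph, semi-transparent and isosurface volume rendering
    with Z-buffer compositing of beam and block polygons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    oro.nifti,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'cli.R'
    'constructors.R'
    'contours.R'
    'filters.R'
    'hounsfield.R'
    'io-dicom.R'
    'io-volume.R'
    'phantoms.R'
    'rendering.R'
    'resampling.R'
    'segmentation.R'
    'utils.R'
    'zzz.R'
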