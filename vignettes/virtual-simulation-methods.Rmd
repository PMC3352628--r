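---
title: "Methods: CT segmentation and virtual-simulation rendering in ctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT segmentation and virtual-simulation rendering in ctsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsim)
```

## Scope and data model

`ctsim` implements the computation stack of a radiotherapy *virtual
simulator*: given a CT volume of the patient, it segments anatomical
structures semi-automatically from a single seed point, measures and
manipulates the resulting contours, resamples anisotropic voxel grids to
isotropic ones, and renders the volume as a digitally reconstructed
radiograph (DRR), a semi-transparent composite, or a shaded isosurface with
beam/block polygons composited over it.

The central object is the `VoxelVolume`: a 3D array of Hounsfield units (HU)
in `(slice, row, column)` order with spacing `(dz, dy, dx)` and origin
`(z, y, x)` in millimetres.  Conventions used consistently everywhere:

* a voxel's world coordinate is its **centre**; voxel `(i, j, k)` (1-based)
  sits at `origin + (c(i,j,k) - 0.5) * spacing`, so an axis with `n` voxels
  spans a world extent of exactly `n * spacing` (half-open cells);
* axial stacks are ordered ascending in `z` (patient axis).  No patient
  orientation metadata is interpreted beyond that ordering;
* HU values are clamped on ingest to the 12-bit scanner range
  `[-1024, 3071]` — 4096 integer values.  Clamping (rather than rejection)
  mirrors what scanners themselves provide.

The HU scale itself is the affine remap of linear X-ray attenuation fixing
water at 0 and air (zero attenuation) at -1000:

```{r}
huFromAttenuation(0.19, 0.19)   # water
huFromAttenuation(0,    0.19)   # air
```

The implementation groups the arithmetic as `1000 * ((rho - rho_w) / rho_w)`
so both anchors are exact in floating point, not merely close.

## Segmentation

Segmentation is the package's core.  The user supplies one seed voxel; the
per-slice pipeline is

1. **window threshold**: object pixels are those with
   `low <= HU <= high`.  A pixel exactly at the bound is *object* (the
   `>=` rule); the historical constant 20–70 HU window is the default, but
   every structure is segmented with an organ-appropriate window (lungs for
   instance live near -800 HU, so a literal 20–70 HU window cannot capture
   them — the window is deliberately a free parameter);
2. **majority smoothing** (optional, default 3x3): the binary mask is
   replaced by the box-mean >= 0.5 vote.  This suppresses isolated noise
   pixels without the feature blurring a grey-level smoothing of the image
   itself would cause;
3. **small-region suppression**: every 8-connected object component with
   in-plane area at most 6 cm² (configurable) is removed.  This is the
   "inside point" safeguard: small bright spots near the seed must not
   capture the tracker;
4. **seed resolution**: a seed on a surviving region is used directly; a
   seed on a *suppressed* region is retargeted to the largest surviving
   region; a background seed is relocated by growing the background region
   around it until it first touches an object region, then moving strictly
   inside that region (all four axial neighbours object) so tracking never
   starts on an unstable edge pixel;
5. **Moore boundary tracking**: 8-neighbour boundary following with a
   clockwise neighbour scan starting from the backtrack direction, i.e. the
   object is kept consistently on one side.  Termination uses Jacob's
   criterion in the "first move repeats" form: the walk stops when it is
   about to retrace its first step from the starting pixel.  This is robust
   where "stop when the start pixel is reached" is not (the start pixel of
   a spur is legitimately visited twice).  Every emitted pixel is an object
   pixel 4-adjacent to background, which is also the morphological
   definition (object minus 4-erosion) the tests compare against;
6. **fill and propagate**: the traced chain is rasterised by pixel-centre
   inclusion (centres strictly inside the polygon, plus the chain pixels
   themselves), and the fill's centroid becomes the seed of the next slice.
   Tracking proceeds in both stack directions until the structure vanishes.

Two guards make the 3D pass conservative: on every slice after the first
the chosen region must overlap the previous slice's fill (otherwise the
tracker would happily jump to the *other* lung once the first one ends,
since both share a window), and a structure that disappears produces a
warning record rather than an error.

The returned mask is exactly the rasterisation of the returned contours, so
contour and mask representations are interchangeable.  A consequence worth
knowing: interior holes (a bright vessel inside a lung, say) are filled,
because the traced outer contour is the definition of the structure.

**Region growing** (`regionGrow`) is provided both as the relocation
engine's 2D analogue and as a standalone 3D tool.  A voxel joins the region
when its grey-level difference to an adjacent already-accepted voxel is at
most `delta`; the accepted set is the order-independent closure of that
relation (computed by synchronous sweeps, so no visit-order artefacts).
The comparison is inclusive — `delta = 0` grows the seed's maximal
constant-value 6-connected component; a strict inequality would reduce it
to the seed voxel alone.  Comparison against the seed value instead of the
adjacent voxel is available as `compare = "seed"`, since the growth
criterion is stated ambiguously in the literature and the two differ on
slow gradients.

## Contours

Contours are ordered `(y, x)` millimetre point lists per slice; closed
contours do not repeat their first point.  Area is the shoelace polygon
area (cm²), periphery the polyline length plus closing segment (cm).

**Decimation** removes `k`% of the points by uniform stride: of `N` points
exactly `floor(N (1 - k/100))` survive, always including the first, as an
ordered subsequence.  The default `k = 20` reproduces the reference
point-count reductions 530→424, 712→569 and 418→334 exactly.  Uniform
stride was chosen over curvature-aware simplification because the goal is
stated as preserving "general presentation", and a uniform rule is the only
one whose output size is exactly predictable.

**Inter-slice interpolation** resamples both key contours to the same
number of equiangular sectors about their centroids (64 by default — the
sector count is not prescribed anywhere, 64 keeps the resampling error of
organ-scale contours well under 1%), matches sector points, and blends them
linearly at fraction `t`; this is equivalent to intersecting the sides of
the triangles spanned between matched points with the intermediate plane.
Winding is normalised to counter-clockwise first, so the result is
independent of input orientation.  The radial resampling assumes each
contour is star-shaped about its centroid; genuinely non-star-shaped or
zero-area contours raise a `degenerateContour` error rather than returning
nonsense.  Branching (one contour splitting into two) is out of scope.

## Resampling

`lerp`/`bilerp`/`trilerp` implement the linear interpolation family — the
triangle kernel `h(x) = 1 - |x|` — with corner naming `p_xyz` (first digit
x).  The printed source of the trilinear formula this package follows
contains an obvious typo (one corner appears with two different weights and
another is missing); the implementation uses the standard tensor-product
form, which reduces exactly to the bilinear formula on each face and whose
weights sum to one (every output is a convex combination of its 8 corners).
Extrapolation is refused rather than clamped silently.

`resampleToIsotropic` resamples onto an isotropic grid over the same world
extent (`round(extent / spacing)` voxels per axis).  Sampling past the
outermost voxel centres clamps to the edge value; consequently a linear
ramp is reproduced exactly at all interior sample positions and flattens in
the outer half-voxel border — tests assert exactness on the interior.

## Rendering

All renderers march rays through the volume with trilinear sampling,
clipped to the volume's bounding box.  Depth (`Z`) is the distance along
the ray from its origin plane and **increases away from the viewer**; the
far-plane value fills the depth buffer where no surface exists.

* **DRR (transparent mode)**: midpoint Riemann sum of the attenuation
  coefficient `K(HU)` along each ray and Beer–Lambert transmission
  `I = I0 exp(-sum K dt)`.  On a homogeneous slab of thickness `D` with 100
  steps this reproduces `I0 e^{-KD}` to machine precision, because the
  midpoint rule is exact for a constant integrand.
* **Semi-transparent**: front-to-back accumulation
  `I = sum C_i a_i prod_{j<i}(1 - a_j)` with per-sample opacities, early
  termination once residual transparency drops below 1e-3, and the depth
  buffer latched where accumulated opacity first crosses 0.5.  Front-to-back
  order (rather than back-to-front integration) is chosen for the early
  termination; the two are algebraically identical for the emitted sum.
* **Isosurface**: first sign change of `HU - isovalue` between consecutive
  samples, refined by one linear sub-step; Lambertian shading `|g . L|`
  with the normal from central differences (half-voxel offset) and a
  headlight default.
* **Polygon compositing**: beam/block polygons are planar; each is
  projected, pixels inside the projected outline get the polygon depth from
  an exact ray–plane intersection, and the polygon is drawn where it is no
  deeper than the volume's first surface (`Z_P <= Z_V`; ties drawn).  With
  depth increasing away from the viewer this realises "nearer wins" — the
  stated meaning of the visibility rules — even though the rule is
  sometimes written with the opposite symbol under an inverted Z axis.
  Visible pixels blend `(1-w) image + w colour` with `w = 0.5` by default
  (the mixing ratio is unspecified in the source material; 0.5 is the
  symmetric choice).  Edge-on polygons are skipped with a warning
  attribute.

## Phantoms: what the synthetic data does and does not show

Two generators produce all test data; both voxelise analytic shapes by
centre inclusion (voxel centre inside the surface → foreground), the
simplest rule that is exactly testable.

The **verification phantom** is a 120 mm water cube holding 2 mm spheres on
a regular grid, scanned at 1 mm slices into 120 slices of 512 x 512 — the
classic geometry-accuracy object.  The sphere pitch is nowhere stated for
the original; 10 mm centre-to-centre is the package default and is
configurable.

The **thorax phantom** is an elliptic soft-tissue cylinder (40 HU) on air
(-1000 HU) holding two ellipsoidal lungs (-800 HU) and a bone spine
cylinder (700 HU), sized proportionally to the requested extents (at the
default 256 x 384 x 384 mm: body 100 x 138 mm semi-axes, lungs
90 x 56 x 44 mm, spine radius 15 mm).  The tissue values are plausible
round numbers chosen far apart so threshold windows can be varied freely.
Optional i.i.d. Gaussian HU noise (a deliberately simple stand-in for the
high-frequency statistical noise of real scanners) is added under the
spec's seed, making generation a pure function of the spec.  Ground truth:
`left_lung`, `right_lung` and `spine` are pairwise disjoint;
`body` is the external outline and *contains* the organs, because that is
what a skin/body segmentation recovers and is measured against.

Passing the recovery tests (Dice >= 0.95 noiseless, >= 0.90 at 20 HU noise
on a 128 x 256 x 256 grid) shows the pipeline is geometrically faithful and
noise-tolerant under known-contrast conditions.  It does **not** show
robustness to the things real CT adds: partial-volume gradients at organ
boundaries, beam hardening and reconstruction artefacts, anatomical
concavities beyond mild ellipsoid overlap, or contact between structures of
similar HU.  The constant-HU interiors also make the threshold windows
unrealistically easy to choose.

## Numerical choices and degenerate inputs

* Connected components are 8-connected in-plane (4-connected labelling
  plus a union-find merge across diagonal label contacts), 6-connected in
  3D.
* Polygon rasterisation uses even-odd pixel-centre inclusion with a
  sub-nanometre test-point offset to break centre-on-edge ties; chain
  vertices are included explicitly, which makes
  mask → trace → fill an exact round trip for hole-free regions.
* Ray–edge intersection in the equiangular resampler tolerates `1e-9`
  in the edge parameter so rays through shared polygon vertices hit one of
  the two incident edges despite rounding.
* A single-pixel region traces to a legitimate one-point closed contour;
  degenerate closed contours (< 3 points) have zero area rather than being
  rejected, since raster traces produce them naturally.
* Histogram thresholding smooths the windowed histogram with a width-5
  moving average and returns the deepest interior valley; images whose
  histogram mass cannot bracket a valley (constant or single-spike input)
  fall back to the window midpoint.
* All error conditions are typed conditions (`ctsim_ioError`,
  `ctsim_inconsistentSpacing`, `ctsim_noObject`, …) so callers and tests
  can discriminate failure modes.

## File formats

DICOM series reading is implemented in-package (explicit/implicit VR little
endian, single-frame 16-bit CT slices) and validated in the test suite
against series written by an independent reference writer; slices are
sorted by patient z and a non-uniform inter-slice spacing — the signature
of a missing slice — is a hard, named error.  NIfTI-1 I/O goes through
oro.nifti with int16 storage, which round-trips 12-bit HU data losslessly.
The `raw_json` fixture format (int16 little-endian block plus a JSON
sidecar with shape/spacing/origin) exists so tests and the command-line
tools never need binary container dependencies.

## Problem sizes used by the shipped checks

The test suite exercises the full-scale verification phantom
(120 x 512 x 512) and the default thorax (128 x 256 x 256, both noise
conditions); unit tests run on a proportionally scaled 16 x 64 x 64 thorax,
where the spine is only ~2.5 pixels in radius and its recovery bar is
accordingly lower (raster quantisation, not algorithm error, dominates at
that scale).  Oracle-equivalence checks run on 100+ random masks and
volumes per operation.
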