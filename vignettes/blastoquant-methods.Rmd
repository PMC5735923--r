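---
title: "Quantifying bovine blastocyst morphology from brightfield micrographs"
author: "blastoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bovine blastocyst morphology from brightfield micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastoquant)
```

## The problem

Bovine embryos produced in vitro are graded by eye under a stereomicroscope
into three IETS quality classes (1 excellent/good, 2 fair, 3 poor). The
grade drives real decisions — which embryos to freeze, which to transfer —
yet it depends on the embryologist's experience and state on the day.
`blastoquant` implements an automated alternative: from a single brightfield
micrograph of a day-7 blastocyst it extracts 36 quantitative variables
describing the embryo's texture, inclusions, intensity distribution, and
inner-cell-mass (ICM) geometry. These variables are designed as inputs to
downstream statistical or machine-learning models; the package deliberately
stops at the feature vector and does not grade embryos itself.

## Pipeline overview

Every image passes through the same fixed sequence:

1. **Standardization.** The image is converted to 8-bit greyscale (BT.601
   luma weights), forced to the 0.75 height/width proportion — a 1280x1024
   frame loses exactly its 64 top rows — resized to 640x480, and
   contrast-stretched so that 1% of pixels saturate at each histogram tail.
2. **Segmentation.** A Sobel gradient magnitude is rescaled to 0..255 and
   thresholded at 128. A circular Hough transform (CHT) then searches the
   binary edge image twice — radii 100–150 px for early blastocysts, then
   150–250 px for expanded ones. The better-scoring circle wins, ties going
   to the larger radius. The detected circle defines three regions:
   **ER** (radius + 5 px, zona pellucida included), **RR** (radius − 40 px,
   trophectoderm excluded) and **TE** (ER minus RR, the trophectoderm
   annulus).
3. **Feature extraction.** Four families of variables:
   co-occurrence texture of RR and TE (variables 1–8), dark/light inclusion
   circles (9–16), Otsu and first-order intensity statistics (17–31), and
   watershed/ICM shape descriptors (32–36).

## Models and statistics

### Grey-level co-occurrence texture

Each region is quantized to 8 grey levels spanning the min–max of its
masked pixels, and the joint distribution $p(i,j)$ of level pairs at offset
$d = 1$, $\theta = 0^\circ$ (one pixel to the right) is accumulated over
pairs whose two pixels both lie inside the region mask. Four statistics are
reported:

$$\mathrm{Contrast} = \sum_{i,j} |i-j|^2\, p(i,j), \qquad
\mathrm{Correlation} = \sum_{i,j} \frac{(i-\mu_i)(j-\mu_j)\,p(i,j)}{\sigma_i \sigma_j},$$

$$\mathrm{Energy} = \sum_{i,j} p(i,j)^2, \qquad
\mathrm{Homogeneity} = \sum_{i,j} \frac{p(i,j)}{1 + |i-j|}.$$

A constant region has zero contrast, unit energy, unit homogeneity and
undefined correlation (recorded as NaN, never silently replaced by 0). The
homogeneity denominator is $1+|i-j|$ — the only form for which a diagonal
co-occurrence matrix attains the documented value of 1. The offset, the
number of levels, and min–max versus fixed-range binning are configurable
through `pipeline_config()`; the matrix is not symmetrized, and
probabilities are normalized by the total pair count.

### Inclusion circles

Small dark and light circular structures (extruded blastomeres, vacuoles,
debris) are detected on the ER image by a polarity-aware Hough accumulator:
every pixel whose gradient magnitude exceeds 5 intensity units/px votes, at
each candidate radius $r$, for a centre at $p \mp r\hat g$ (minus for dark
circles, since the gradient points from dark to bright). Radius slices are
smoothed (sigma 1 px) and normalized by the perimeter so a complete circle
with a moderately contrasted edge scores about 1. Peaks above
$3(1-\mathrm{sensitivity})$ — sensitivity 0.935 for radii 4–8, 0.94 for
9–15, the mapping from sensitivity to threshold being implementation-defined
— are accepted greedily with non-maximum suppression, then **verified**:
a candidate must be darker/brighter than its surrounding ring by at least
22 intensity units in *every* angular quadrant, have a homogeneous interior,
and be supported by polarity-consistent radial edges at the claimed radius
over at least 8 of 12 angular sectors. Verification is what separates true
inclusions from texture blobs, stripes (e.g. the trough between zona and
background), and partial arcs of larger structures such as the ICM boundary.
The accumulator also evaluates guard radii just outside the requested range
so that a circle slightly larger than the range is claimed by its own radius
rather than mis-counted at the range boundary.

Each detector reports its count and the mean grey intensity over a mask of
discs placed at the detected centres with the *mean* detected radius; an
empty detection reports intensity 0 by convention (flagged in
`quality_flags`).

### Intensity statistics

Sum ER is the fraction of ER pixels above the Otsu threshold of the ER
histogram, divided by the total embryo area (the ER pixel count — a
pixel-exact definition that remains valid when the crop is clipped at the
image border). The per-region statistics are the sample standard deviation
(with $n-1$ denominator), mean, mode (ties toward the smallest intensity),
and the fractions of pixels at intensity ≤ 25, ≥ 230, and within ±10 of
the region mean — all inclusive bounds, all divided by the total embryo
area.

### Watershed and ICM shape

The intensity surface of the isolated embryo (dark = deep) is segmented by
an unseeded watershed transform with the background raised to a plateau
above the 8-bit range so it forms no interior basin. No marker control or
minima suppression is applied, because raw basins are the definition of the
region count WSN; a Gaussian pre-smoothing option exists but is off by
default. The basin with the largest pixel count is taken as the ICM — in
real micrographs the ICM is a relatively homogeneous dark region and
collects the deepest, largest basin — and its area, convex-hull area
(pixel centres inside the smallest convex polygon), moment eccentricity
(focal distance over major axis of the same-second-moments ellipse:
0 = circle, 1 = line segment), and mean intensity are reported.

Because the watershed is unsuppressed, WSN is sensitive to noise and to the
exact platform implementation; reproductions of WSN on other software
should be expected to differ, which is why the package's own validation
relies on synthetic phantoms with known ground truth rather than on
matching any particular deposited value.

### Grading utilities

`modal_grade()` returns the majority of three IETS grades; a three-way
disagreement (1, 2, 3) has no mode and resolves to the median, grade 2 —
implemented as the middle order statistic, which realizes both rules at
once. Agreement between the three raters is measured by Fleiss' kappa, with
Light's kappa (mean pairwise Cohen) reported alongside because published
kappa values do not always name the variant.

## The synthetic phantom generator

`phantom_spec()`/`generate_phantom()` render a seeded, fully reproducible
blastocyst phantom with ground truth: a bright background (220), a textured
trophectoderm annulus (mean 140, sd 15, blob scale 3 px) spanning the outer
40 px of the embryo, a bright zona ring just inside the rim, a blastocoel
(170) with a gentle radial dome (12 units) and fine mottle (sd 6, scale
2 px), a homogeneous dark elliptical ICM (intensity 80, semi-axes 0.30 r
and 0.19 r by default) with a thin bright refractile fringe at its border,
optional dark/light circular inclusions, Gaussian optical blur (sigma 0.8
px in the standardized frame) and additive sensor noise (sd 2). Phantoms
default to 1280x1024 so that standardization exercises the 64-row crop and
2x downscale path; all geometry and ground truth are expressed in the
standardized 640x480 frame.

Two rendering choices deserve explanation. First, the ICM is composited
*after* the optical blur with a crisp (sigma 0.6 px) edge: the capture
protocol this generator emulates places the focal plane through the widest
section of the ICM, making its boundary the sharpest structure in the
frame. Second, the ICM carries a thin bright fringe, the refractile
diffraction line that hugs dense cell masses in brightfield images. Both
features matter for the watershed: the fringe forms a natural watershed
wall, so the ICM basin closely follows the true ellipse instead of
absorbing a ramp of blurred boundary pixels. The blastocoel mottle, in
turn, is what fragments the bright interior into many small basins — the
same mechanism that makes the homogeneous dark ICM the largest basin in
real images.

What the phantoms do **not** emulate: uneven illumination fields,
degenerated or collapsed embryos, multiple embryos per frame, optical
vignetting, and the cellular substructure of a real trophectoderm. Passing
the phantom recovery suite therefore demonstrates that the implementation
is internally correct and robust to noise, texture and JPEG compression at
the stated levels — not that every real micrograph will segment correctly.

## Validation results the test-suite computes

* Embryo radius recovered within ±2 px across radii 110–245, through the
  full standardize → gradient → binarize → detect path, including the
  1280x1024 crop path and JPEG-compressed phantoms.
* Inclusion counts exact for planted inclusions with ≥ 30 intensity-unit
  contrast and ≥ 4 px separation on uniform-interior embryos (the
  count-recovery condition; on fully textured phantoms the detector also
  reports genuine texture-blob circles, as it does on real images).
* ICM basin area within ±10% of $\pi a b$ and eccentricity within ±0.05 of
  $\sqrt{1-(b/a)^2}$ on noiseless phantoms with realistically elongated
  ICMs ($b/a \le 0.8$).
* Every GLCM statistic, intensity fraction, the deviation, and the
  circle-mean intensity agree with independent brute-force oracles.

## Numerical choices and degenerate inputs

* Quantile convention for the contrast stretch: type-1 (inverse ECDF)
  order statistics; with heavily tied 8-bit histograms the saturated mass
  can exceed the nominal 1% by the mass of one tied value.
* Binarization boundary: ≥ 128 counts as edge.
* CHT tie-break: larger radius on equal metrics; the detected radius is
  clamped to [100, 250]; the accumulator metric is the fraction of the
  annulus covered by edge pixels, and detections below 0.25 raise a
  structured detection error.
* Eccentricity uses raw second central moments without the 1/12-pixel
  correction, so a one-pixel-wide segment attains exactly 1 and a
  symmetric disc exactly 0. Near-circular regions are ill-conditioned: a
  ±1 px fluctuation of a basin boundary moves the eccentricity of a
  circular region by ~0.15, which is why circularity claims should be made
  on the axis ratio, not the eccentricity.
* Empty regions, constant regions (degenerate Otsu, zero-variance
  correlation), single-pixel regions (undefined deviation) and empty circle
  sets all produce documented values plus `quality_flags` entries, never
  silent zeros (the one deliberate exception: the empty-circle-set mean
  intensity is 0 by table-layout convention, with a flag).
* Coordinates are 1-based row/column indices (R convention), row = y from
  the top, column = x from the left; all published pixel offsets (+5, −40,
  64 rows) are unaffected by the origin choice.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
single phantoms at 640x480 or 1280x1024, recovery sweeps over ~15 phantoms,
and grade tables of 482 synthetic items — sizes chosen so the whole
validation runs in minutes on one CPU while still exercising every
code path at the pipeline's native image resolution.

## Known limitations

* The GLCM offset, the watershed input (raw vs gradient image, ER vs RR),
  and the sensitivity-to-threshold mapping of the circle finder are not
  uniquely determined by the published description of the method; this
  package fixes defaults (d = 1, θ = 0°; raw ER surface; the mapping above)
  and exposes them in `pipeline_config()`. Per-image numerical agreement
  with tables produced by other implementations is therefore not expected,
  and the validation targets parameter recovery on phantoms instead.
* XLS reading is not provided; the deposited-layout reader accepts CSV with
  the same columns.
* Resizing uses bilinear interpolation with anti-aliasing.
* One embryo per frame, approximately centred, is assumed throughout.
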