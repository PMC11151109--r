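---
title: "dtcmorph: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dtcmorph: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcmorph)
```

# The problem

The *C. elegans* distal tip cell (DTC) caps the gonad arm and acts as the
germline stem-cell niche. Its adult morphology — a bright cell body at the
distal end and a plexus of very dim, thin processes reaching proximally
among the germ cells — is informative but awkward to quantify: the useful
signal spans orders of magnitude of intensity within one field of view, and
every gonad arm is curved differently, so neither raw intensities nor raw
coordinates are comparable across specimens. `dtcmorph` makes both
comparable by construction: intensities are normalized onto a common
display range, geometry is resampled onto a common straightened axis, and
all downstream measurements (markup distances, Sholl profiles) are taken in
that common frame, in micrometres.

Coordinates everywhere are 0-based `(x, y)` with x rightward, y downward
and pixel centers at integer positions; a raster value at `(x, y)` lives at
`matrix[y + 1, x + 1]`. Calibration is carried as micrometres per pixel
(isotropic in XY) and micrometres per Z step, and an absent calibration is
an error rather than a default — a silently assumed pixel size would
corrupt every distance the package reports.

# Image optimization

`optimizeImage()` composes four steps, each recorded with its numeric
parameters in the image's provenance list so a result can be audited or
replayed:

1. **Maximum projection** across Z (`maxProject()`).
2. **Background subtraction.** The background is the mean of the darkest
   `ceiling(f·N)` pixels (`backgroundFraction` f, default 0.001). Ties at
   the cutoff intensity are resolved by averaging over *all* pixels at or
   below the cutoff, which makes the estimate a pure function of the
   intensity histogram — reordering pixels cannot change it. The result is
   subtracted and clamped at zero: the darkest pixels *define* zero signal,
   so nothing is shifted below it.
3. **Gamma transformation** `v -> v^gamma` on intensities normalized to
   [0, 1] by the image's own post-subtraction maximum. Default
   `gamma = 0.5`. A gamma below 1 is monotone (it never reorders pixels)
   and compresses ratios — a pair of pixels at ratio `R >= 1` maps to
   `R^gamma <= R` — which is exactly what lifts dim processes into
   visibility next to a bright body.
4. **Rescale** to `[0, outputMax]` (default 65535). For any non-constant
   input the output minimum is exactly 0 and the maximum exactly
   `outputMax`.

Two choices here were genuinely open and are worth recording. First, the
order: subtraction happens *before* gamma. Applying gamma first would boost
the background along with the signal and make the darkest-pixel estimate
scale-dependent; subtracting first keeps the background estimate in the
raw-intensity units of the camera. Second, normalization uses each image's
own maximum rather than a shared absolute scale: the goal is that all
specimens end in the *same display range*, not that absolute intensities be
preserved (they are deliberately not — provenance retains the parameters if
the transform must be inverted or compared).

Closed-form consequence, used by the tests: a pixel at normalized intensity
0.25 maps to exactly `0.5 * outputMax` under `gamma = 0.5`, and a
dim-to-bright amplitude pair `(a, b)` lands at the output ratio
`(b/a)^gamma`. With the synthetic defaults (processes ~150, body ~50000)
that puts optimized processes at about 5.5 % of the ceiling — an ~18-fold
relative boost over their linear 0.3 % — which is the level the validation
asserts.

# Straightening

The user supplies the arm's path as ordered control points, *distal end
first* (mirroring the draw-direction convention that puts distal at left);
the direction is trusted, never inferred, because automatic flipping would
silently invert every distance downstream.

`resamplePath()` realizes the segmented line as a natural cubic spline
through the control points, parameterized by chord length (two points fall
back to straight interpolation), and resamples it at uniform arc-length
spacing (default 1 px) by dense evaluation (at least 20 samples per chord
pixel) followed by inverse interpolation of the cumulative arc length. The
output *includes both endpoints*: a 100 px segment at spacing 1 yields 101
points. Tangents come from the spline's analytic derivative rather than
finite differences, so normals carry no discretization jitter.

`straightenImage()` samples the image by bilinear interpolation along the
unit normal of the path at each resampled point, at offsets
`-(w-1)/2 ... +(w-1)/2` for an odd band width `w` (default 121 px).
Column 0 is the distal point. Two numerical details matter:

* Fractional bilinear offsets below 1e-9 are snapped to the grid, so
  sampling at integer coordinates is bit-exact; straightening along a
  horizontal path therefore equals the axis-aligned crop exactly, which is
  the anchor test of the geometry.
* Samples falling outside the image are zero-filled and counted in the
  result's `"clipped"` attribute rather than erroring, because a band
  margin will routinely graze the border near a curved distal tip.

`cropFixedBox()` then forces every specimen of a batch onto one geometry
(default 550 × 120 px, about 119 × 26 µm at 0.2167 µm/px): left-anchored
horizontally (the distal origin is never cut), zero-padded or truncated on
the right, and vertically centered on the band's center row with the odd
spare row at the bottom. Uniform dimensions are the precondition both for
montages and for comparing X-axis distances across specimens.

The projection is straightened, not the individual Z planes: markup and
Sholl operate on the 2D projected image, and straightening each plane
before projecting would only re-interpolate noise without changing any
measured quantity in this pipeline.

# Markup

The distal origin is defined geometrically: the user places a circle
tangent to the curve of the distal end, and the origin is the circle's
leftmost point, `center.x - radius`. On a straightened image the gonad axis
is horizontal by construction, so the leftmost point *is* the inner-arc
tangency point; adopting it as a fixed rule (rather than a visually chosen
tangency) keeps the origin reproducible between users.

Every mark is logged as a signed 1-D distance along X,
`(x - origin_x) * pixelSize` µm, positive proximal. The Y coordinate is
recorded in the table but excluded from the distance by contract — the
distal–proximal axis is the biologically meaningful coordinate after
straightening. The feature vocabulary defaults to `branchpoint`, `punctum`,
`fragment`, `process_endpoint`, `nucleus_center`, `distal_origin` and a
free `other` slot, and is configurable: the slate of useful features
differs between reporters, so the vocabulary is a parameter rather than a
fixed enumeration. The nucleus circle contributes its center as a
`nucleus_center` mark and its radius (px and µm) as logged header
parameters.

`measureAllMarkups()` writes `<specimen>.markup.tsv` — the automatic
filename keyed to the specimen id prevents sample–data mismatches in large
batches. The six data columns are exactly
`specimen_id, feature_type, index, x_px, y_px, distance_um`; per-type count
rows reuse the `index` column with NA coordinates, and the anchor/nucleus
circles plus pixel size travel in `#`-prefixed header lines, so the full
record (marks, circles, derived values) round-trips through the file to
four decimals. Derived values are pure functions of the stored marks,
enforced by the class validity on every construction, including re-reads.

# Sholl analysis

`binarize()` thresholds strictly above a cutoff chosen by Otsu's method
(between-class variance maximization over the 16-bit histogram, via
EBImage) or supplied as a fixed value; the method and value are recorded on
the mask.

`shollProfile()` re-implements bitmap Sholl counting explicitly rather than
delegating to an external plugin, so the algorithm is fixed and testable:
for each radius `r_i = i * stepUm` (default 1 µm, matching the standard
1 µm radius spacing; radius 0 is degenerate and excluded), the circle is
sampled at angular increments giving arc steps of at most 0.5 px, each
sample looks up the mask at its nearest pixel, and one *intersection* is
one maximal connected run of foreground samples along the closed circle —
runs crossing the 0/2π seam are merged, and a fully foreground circle
counts as 1.

The sampling contract: at 0.5 px arc steps, any foreground run or gap at
least 2 px wide along the circle receives at least two samples, so the run
count cannot alias. The package therefore documents a minimum structure
width of 2 px after binarization (and the synthetic generator draws all
processes at least 2 px wide). Two consequences are deliberately part of
the contract rather than hidden: structures thinner than ~1 px may alias,
and nearest-neighbor lookup can round a sample onto a foreground pixel up
to half a pixel diagonal (√2/2 px) away, so counts are guaranteed zero only
beyond the farthest foreground pixel *plus that reach*. Validation compares
the standard sampling against an independently written oracle at 10× finer
angular steps on randomized ray and annulus-sector fixtures built to keep
all crossings transversal — concentric (tangential) boundaries are excluded
by design, because no sampled counter is alias-free when a test circle
grazes a boundary at sub-sample scale.

The center point is user-defined input throughout (in synthetic tests, the
ground-truth body centroid); the package does not guess it.

# The synthetic generator

`generateDtcStack()` is first-class, tested code, not a fixture: it renders
a calibrated scene with complete ground truth so that every stage —
calibration handling, optimization, straightening, markup distances, Sholl
counts — can be validated end-to-end without microscope data.

The default scene emulates the acquisition regime the pipeline targets:
0.2167 µm pixels, 0.5 µm Z steps over 7 planes, a gently curved centerline,
a Gaussian cell body peaking at 50000 counts near the distal tip, 3 px-wide
processes at 150 counts (a 333-fold body-to-process ratio — the
orders-of-magnitude regime; the validity requires at least 50-fold),
branches at prescribed arc positions with recorded branchpoints, puncta as
small Gaussian spots on the centerline, disconnected fragment segments
offset from the arm, a Gaussian axial intensity profile across Z, a flat
background of 100 counts and additive Gaussian noise (sd 20, the low-noise
EMCCD regime; body + background + 5·sd must stay below 2¹⁶, so nothing
saturates). Noise is additive Gaussian rather than Poisson to keep
closed-form checks exact; Poisson shot noise is out of scope. All geometric
truth is stored in pixels *and* arc-length micrometres simultaneously, so a
unit mix-up fails tests loudly rather than rescaling quietly.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: optical blur beyond the Gaussian spots (no PSF
convolution), germ-cell or gut-granule confounder fluorescence, depth-
dependent attenuation, anisotropic Z sampling artifacts, and annotator
error beyond rounding marks to integer pixels. Recovery results on
synthetic data bound the pipeline's geometric error (about half a pixel,
from click rounding), not a human's marking error.

A second layout (`layout = "rays"`) renders k straight rays from the body
centroid — the classical Sholl benchmark — linking the generator directly
to the intersection counter: the noise-free binarized projection must count
exactly k at mid radii.

# Files and formats

The interchange image format is multi-page grayscale TIFF (8/16-bit), read
with page order as Z order and the filename stem as the specimen id. The
CRAN TIFF writer does not emit resolution tags, so calibration written by
this package (pixel size, Z step, bit depth, intensity scale, provenance)
travels in a JSON sidecar `<image>.meta.json`; on reading, precedence is
explicit override > TIFF resolution/description tags (honored when present,
e.g. on ImageJ-written files) > sidecar > error. Annotations and
straightening paths are JSON; markup tables are TSV; Sholl profiles are CSV
(`radius_um, intersections` with `#` header lines); all round-trip exactly
or to documented precision. Proprietary microscope formats are not read —
convert to TIFF upstream.

`runPipeline()` writes, next to its outputs, the fully resolved config
(unknown keys are rejected, so a typoed parameter can never be silently
ignored) and a manifest of MD5 content hashes; re-running an identical
config is byte-reproducible, which the test suite asserts file by file.

# Validation problem sizes

The shipped validation runs entirely on generated data, sized to exercise
every contract while keeping the suite fast: 50 randomized Sholl fixtures
on 151² grids checked radius-by-radius against the fine-sampling oracle;
straightening checked on ~200×90–250×150 rasters (identity, 90°
equivariance, spline-ridge recovery); 100 random images for the background
oracle; synthetic specimens of 420×180×7 at the default calibration for
end-to-end recovery; and a three-specimen batch, run twice, for
byte-reproducibility. `scripts/acceptance.R` recomputes all of these from a
single `--seed`.

# Known limitations

* Straightening is 2D: the projection, not the volume, is resampled.
* Sholl counts are 2D bitmap counts; no 3D Sholl, log-log ramification
  indices or profile fitting.
* The thinner-than-2 px and tangential-boundary caveats above apply to any
  sampled intersection counter; equivalence is claimed with this package's
  documented fine-sampling oracle, not with any external plugin's variant.
* Feature marks are inputs (user-guided method); there is no automatic
  branchpoint or punctum detection.
* Multichannel and time-series stacks are out of scope.
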