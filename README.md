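# dtcmorph

Quantitative morphometrics for the *C. elegans* hermaphrodite distal tip
cell (DTC), as a headless, scriptable R package.

The DTC is the unicellular niche for germline stem cells. In adults it
elaborates a plexus of thin processes that intercalate among dozens of germ
cells, and its shape varies strongly between animals, with development, and
across experimental conditions. Quantifying that shape from confocal
Z-stacks is hard for two reasons: the fluorescence dynamic range spans
orders of magnitude (a bright cell body next to very dim, thin processes),
and every cell is curved differently, so raw images are not comparable.
`dtcmorph` addresses both with a deterministic pipeline that a lab can run
in batch from R or a shell, producing comparable images, per-specimen
measurement tables and Sholl profiles.

## The pipeline

1. **Image optimization.** A maximum projection of the Z-series is
   background-subtracted and contrast-adjusted by a gamma transformation:
   with background *b* estimated as the mean of the darkest fraction of
   pixels (default the darkest 0.1 %),

   *v′ = ((v − b)₊ / max(v − b)₊)^γ · M*

   with γ = 0.5 and display ceiling M = 65535 by default. γ < 1 lifts the
   dim processes relative to the bright body while preserving intensity
   order, and every image ends on exactly the range [0, M], so all
   specimens are directly comparable.
2. **Curve-guided straightening.** The user supplies the curved path of the
   gonad arm (distal end first). The image is resampled along the spline's
   normals so the arm becomes horizontal with distal at left, then cropped
   to a fixed box (default 550 × 120 px) so every specimen in a batch has
   identical geometry.
3. **Feature markup.** Typed marks (branchpoints, puncta, fragments,
   process endpoints, nucleus) are read from an annotation JSON. A circle
   placed tangent to the distal end defines the origin; each mark is logged
   by its signed distance along the X axis, *d = (x − x₀) · s* µm (pixel
   size *s*, positive = proximal), into a tab-delimited table named
   `<specimen>.markup.tsv` automatically after the specimen.
4. **Sholl analysis.** The image is thresholded (Otsu or fixed) and the
   number of intersections *N(r)* of the binary structure with concentric
   circles of radius *r* = *i* · 1 µm about a user-defined center is
   counted: one intersection per maximal connected foreground run along
   each circle.
5. **Synthetic data.** `generateDtcStack()` renders calibrated synthetic
   DTC stacks (0.2167 µm pixels, 0.5 µm Z steps) with full ground truth —
   the basis of every validation in the test suite.

## Worked example

```r
library(dtcmorph)

out <- generateDtcStack(synthParams(seed = 7))   # synthetic specimen + truth
opt <- optimizeImage(out$stack)                  # project + contrast-adjust
ctrl <- out$truth@centerline[round(seq(1, nrow(out$truth@centerline),
                                       length.out = 8)), ]
st <- cropFixedBox(straightenImage(opt, curvePath(ctrl, bandWidthPx = 61L)),
                   360L, 61L, "synth007", pixelSizeXY(opt))
st
#> StraightenedImage 'synth007': 360 x 61 px, 0.2167 um/px, range [0, 6.544e+04]
#>   provenance: straighten -> crop_fixed_box

rec <- markupRecordFromAnnotations(
  renderAnnotations(out$truth, frame = "straightened", bandWidthPx = 61L),
  "synth007", 0.2167)
head(subset(measureAllMarkups(rec), !is.na(x_px)), 8)
#>  specimen_id  feature_type index x_px y_px distance_um
#>     synth007 distal_origin     0    0   30      0.0000
#>     synth007   branchpoint     1   37   30      8.0179
#>     synth007   branchpoint     2  111   30     24.0537
#>     synth007   branchpoint     3  184   30     39.8728
#>     synth007       punctum     1   32   30      6.9344
#>     synth007       punctum     2   78   30     16.9026
#>     synth007       punctum     3  103   30     22.3201
#>     synth007       punctum     4  221   30     47.8907

prof <- shollProfile(binarize(st, method = "otsu"),
                     center = c(23, 30), stepUm = 1, maxRadiusUm = 15)
prof
#> ShollProfile: center (23.0, 30.0) px, 15 radii every 1 um
#>   max 2 intersections; extent 12 um
```

The markup table reads: the first branchpoint sits 8.02 µm proximal of the
distal origin, the second 24.05 µm, and so on — these distances recover the
generator's ground-truth arc positions to within one pixel (0.2167 µm). The
Sholl profile says the thresholded cell crosses the 1–12 µm circles around
the chosen center, at most twice.

Batch processing uses a single JSON config
(`dtcmorph run --config config.json`): each input stack `<stem>.tif` is
paired with `<stem>.path.json` / `<stem>.ann.json`, outputs are keyed by the
same stem, and a `manifest.json` of MD5 content hashes plus the resolved
config make every run traceable and byte-reproducible.

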