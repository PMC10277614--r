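---
title: "Methods: overview figures from whole-slide images and cohort summarisation"
author: "slideOverview"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overview figures from whole-slide images and cohort summarisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideOverview)
```

## Purpose and scope

`slideOverview` turns pyramidal whole-slide images (WSI) into patient-level
pathology overview figures — low-magnification tissue overviews with
physically calibrated scale bars, marked region-of-interest (ROI) insets, and
labelled sample-by-stain grids — and summarises cohort-level immunophenotype
tables of the kind produced when screening xenograft pipelines for EBV-driven
B-cell lymphoproliferations. This vignette records the procedures, the
parameters that matter, and the design decisions taken where more than one
reasonable convention existed.

## The coordinate and calibration model

A pyramidal slide is a stack of pre-computed resolutions: level 0 is the full
scan and level *k* carries a downsample factor *d_k* (strictly increasing,
*d_0* = 1), with level dimensions within ±1 px of `level0_dims / d_k`. All
public spatial arguments are half-open rectangles `[x, x+w) × [y, y+h)` in
**level-0 pixels** (`RegionL0`), origin top-left. One frame for everything is
the single most effective defence against off-by-one-downsample bugs;
level-space coordinates exist only inside `readRegion`.

Two policies follow from how pathologists use these images:

- **Regions are clamped, not rejected.** ROIs near tissue edges are routine;
  only a region that clamps to nothing is an error.
- **No upsampling, anywhere.** A request larger than the available data
  returns the finest data that exists. Fabricated resolution misleads the
  reader of a histology figure.

Micron calibration (MPP, µm per level-0 pixel) is taken from a JSON sidecar
(`<slide>.meta.json`, keys `mpp_x`/`mpp_y`). TIFF resolution tags have
ambiguous unit dialects across writers, so the sidecar is authoritative and
bit-exact; a slide without one simply has no calibration, and everything
physical (scale bars, micron-specified ROIs) is suppressed or errors rather
than guessed. Reading is backed by the `tiff` package, which handles the
pyramidal multi-page TIFFs this package targets; vendor formats that need a
dedicated backend are out of scope here and fail with a clear format error.

When level dimensions are not exact divisors, the per-level downsample is
estimated as the candidate among `w0/wk`, `h0/hk` and their mean that keeps
both axes within the ±1 px invariant — a single-axis ratio can overstate the
factor on coarse levels.

## The synthetic-slide generator

Real scanner files are large, proprietary and unnecessary for testing
geometric contracts. The generator (`SlideSpec`/`generateSlide`) writes
uncompressed multi-page TIFFs whose every level is **rendered analytically at
its own scale** — shape membership is evaluated at each pixel centre in
level-0 coordinates — rather than resampled from level 0. Level-consistency
tests therefore exercise the reader, not the generator. Alongside each slide
it writes the calibration sidecar and a ground-truth JSON holding the exact
integer union bounding box of the tissue shapes and the ROI rectangle.

What it emulates: a white slide background; one or more elliptical tissue
fragments with saturated, stain-specific fill colours (the 16-label panel in
`stainPanelSuite` mirrors an immunophenotyping stain set: H&E, CD45, AE1/AE3,
CD20, CD79A, CD3, BCL2, CD56, CD10, BCL6, MUM1, CD138, CD30, EBER, IgK,
IgL); an optional checkerboard ROI with known period for pixel-exact
read-back checks; optional seeded speckle noise (off by default — geometry is
deterministic so exact assertions come first, robustness second).

What it does not emulate: histology texture, staining heterogeneity,
pen marks, coverslip artifacts, focal blur, or multi-specimen slides.
Passing tests demonstrate that the geometry, calibration and rendering
contracts are exact; they do not demonstrate tissue-detection robustness on
degraded real-world scans.

Pyramids are written uncompressed so that identical specs produce
byte-identical files on any platform (strip-organised, as the TIFF writer
emits them).

## Tissue detection

Detection runs on a thumbnail capped at 1024 px (fixed, so the morphology
parameters are scale-stable). Each pixel gets the score

> *s* = max(saturation, 1 − brightness)

which responds to chromogenic stains (brown/purple DAB: saturated) and to
dark hematoxylin on a white background with a single rule across all stain
types. The threshold is Otsu's method on the score histogram (256 bins, via
`EBImage`); the binary mask is closed with a 2 px disc and connected
components smaller than `minComponentFrac = 0.005` of the thumbnail are
dropped. A blank thumbnail (score variance ≈ 0) yields an empty mask with a
warning, and an empty mask falls back to the whole-slide bounding box so
figures always render. The bounding box is expanded per side by
`marginFrac × max(w, h)` and clamped.

This rule is this package's own choice — the "semi-" in semi-automatic is
honoured by a manual `tissue_bbox` override in the figure config, which takes
precedence over detection entirely.

## Overview extraction and scale bars

`extractOverview` reads the crop at the coarsest pyramid level still at least
`targetPx` wide/high and area-averages down so the maximum output dimension
equals `targetPx` exactly; if even level 0 is smaller, the finest data is
returned unchanged. Area averaging (separable overlap-weight products) is
deterministic and anti-aliased; nearest-neighbour never appears in outputs.
One internal subtlety: the finest level that already fits *within* the target
(what `chooseLevel` returns, useful when a capped read is wanted) cannot be
resampled *up* to the exact target without violating the no-upsampling
policy, so the exact-size path deliberately reads one step finer and only
ever downsamples.

Orientation is harmonised with quarter turns plus an optional horizontal
mirror (`Transform`) — serial sections differ by scanner orientation, not
arbitrary angle, and restricting to the dihedral group keeps every coordinate
mapping exact (tested as group identities, pixel-exact).

Scale bars use the nice set {1, 2, 5}·10^k µm. The target physical length is
`targetFrac` (default 0.25) of the rendered width; among candidates whose
drawn width falls in the 10–40 % window the one minimising
|log(candidate/target)| wins. The default fraction reproduces the 1.0 mm bars
conventional on ~5 mm-wide tissue overviews. Labels print millimetres with
one decimal at ≥ 1000 µm and integer microns below. The bar is drawn in a
white margin band appended below the image (6 % of the height), never over
tissue, with a bundled 5×7 bitmap font so output is byte-identical across
platforms. Physical truth — drawn pixels × effective µm/px = nominal length
to within one pixel's worth of microns — is asserted on every rendered
overview in the test suite.

Insets are specified by centre plus a physical width in microns (requiring
calibration: 250 µm at 0.25 µm/px forces a 1000 level-0-px window) and are
square on this call path, matching the usual presentation of
high-magnification crops; an explicit pixel-unit `RegionL0` is the
calibration-free alternative and keeps its own aspect. The ROI rectangle is
annotated on the overview as a 2 px black outline mapped through crop
offset, downsample and transform.

## Figure composition

`FigureConfig` is declarative: an ordered panel list (row-major placement,
grouping is purely the author's ordering), columns, panel size, inset
fraction (default 0.3 of panel width, composited top-right with a 2 px
border), gutter and label band. `layoutDims` fixes the canvas arithmetic;
`composeFigure` writes a lossless PNG plus a JSON manifest recording, per
panel, the crop, level, downsample, scale-bar length and warnings.
Composition is pure — reruns are byte-identical — and degradation is
graceful: an unreadable slide becomes a placeholder panel carrying the error
text, the manifest counts the warning, and the figure completes. Placeholder
panels (uniform light gray, centred text) also represent samples with no
histology available, keeping cohort grids complete.

## Cohort summarisation

The phenotype table uses a closed vocabulary: `+`, `-`, `#` and
`unavailable`. The `#` call (focal/partial staining) is kept as its own
category and never folded into `+` or `-`; collapsing it would discard
information and no published legend licenses either merge. Ig light-chain
codes classify as kappa-only (`K`), lambda-only (`L`) or dual when a second
chain appears in parentheses (`K (L)`, `L (K)`). Evaluable rows are those
with histology (total minus fully-unavailable rows).

Percentages are formatted by rounding half away from zero to one decimal —
the convention that matches how count-derived rates are reported clinically
(`proportionPct(6, 68)` is "8.8%").

The two-group rate comparison is the plain Pearson chi-square on the 2×2
table, **without** continuity correction, df = 1, two-sided, α = 0.05. Where
a published comparison states only "ns, chi-square test", the uncorrected
Pearson form is the minimal assumption; the method string is carried in every
result so the choice is visible in output. The implementation delegates to
`stats::chisq.test(correct = FALSE)`; the test suite checks it against an
independent expected-count computation to 1e-10 on random tables.
Latency/harvest-time comparisons are exposed as thin wrappers over
`stats::wilcox.test` / `stats::kruskal.test` taking user-supplied per-sample
day vectors; no fixture is bundled for them because per-sample values are
not published — only medians — and inventing them would be dishonest.

## Numerical choices and degenerate inputs

- `mapL0ToLevel` floors origins, rounds extents, clamps to ≥ 1 px; round
  trips drift by < 1 downsample per coordinate.
- Area-average weights are exact interval overlaps; outputs are rounded to
  the 8-bit grid once, at the end.
- Generated levels are snapped to the 8-bit grid before writing so every
  level round-trips exactly through TIFF.
- Blank thumbnails, empty masks, disjoint ROIs and unreadable panel slides
  all warn and degrade rather than error; empty-after-clamping regions and
  missing calibration on physical-unit paths are hard errors.
- Scale-bar selection falls back to the globally nearest nice value (with a
  warning) if no candidate fits the width window — possible only at
  pathological aspect ratios.

## Problem sizes

The test suite and the acceptance script run on synthetic pyramids of
roughly 500–3000 px at level 0 with downsamples (1, 4, 16) and on a
12–20-slide randomised sweep for bounding-box recovery; these sizes exercise
every contract (multi-level selection, non-divisor dimensions, clamping)
while keeping a full run to a couple of minutes on one CPU. The geometry is
scale-free — nothing in the implementation depends on absolute pixel counts —
so the same contracts hold at scanner-native sizes.

## Known limitations

- No vendor-format backends beyond pyramidal TIFF; no ICC colour management,
  tile caching, or JPEG2000.
- Tissue detection has no artifact handling (pen marks, coverslips) and
  returns the union box for multi-specimen slides.
- Free-angle rotation, colour deconvolution, stain normalisation and focus
  QC are out of scope.
- The figure composer targets raster output only (PNG/TIFF), not vector.
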