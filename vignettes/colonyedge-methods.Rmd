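---
title: "Edge-detection colony counting: the method, its parameters, and its limits"
author: "ColonyEdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-detection colony counting: the method, its parameters, and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ColonyEdge)
```

## The problem

Colony-forming assays — clonogenic survival after irradiation, tumorsphere
formation by tumor-initiating cells, bacterial CFU plating — all reduce to
the same readout: count roughly circular objects in a photograph and
measure their sizes. Plain intensity thresholding struggles exactly where
these assays live: unstained colonies barely differ from the background
(brightfield or Nomarski), plates are unevenly lit, and debris, bubbles
and scratch marks litter the field. An *edge-based* pipeline sidesteps
much of this: object boundaries are sudden changes in grayscale value and
remain detectable when absolute intensities are uninformative.

## The pipeline

`runPipeline()` applies an ordered stage list to a grayscale image and
then measures the surviving objects. The canonical stage order is:

1. **Background subtraction** — the background is estimated as the
   grayscale opening of the image with a ball-shaped structuring element
   of radius $r$ (the rolling-ball construction: heights
   $\sqrt{r^2-|d|^2}$ over the disk $|d|\le r$) and subtracted. This
   removes illumination trends whose spatial scale exceeds the ball while
   preserving objects narrower than it. Dark objects on a light
   background are handled by inverting first (`lightBackground`), so the
   pipeline always proceeds with bright objects on a near-zero
   background. A useful starting radius is the average object radius;
   note that the estimate penetrates objects *wider* than the ball by
   roughly $w^2/2r$ (for object half-width $w$), so large faint objects
   retain only their edges — which is all the pipeline needs.
2. **Sharpen** — 3×3 high-boost kernel (centre 12, neighbours −1,
   normalized by 4), clipped to the depth range. Accentuates edges before
   gradient extraction; also amplifies sensor noise roughly threefold,
   which matters below.
3. **Sobel edges** — the unclipped gradient magnitude
   $\sqrt{G_x^2+G_y^2}$.
4. **Gaussian smoothing** (σ) — integrates the edge ridge along its
   length while diluting point-like noise responses.
5. **Make binary** — an automatic global threshold (below).
6. **Close + fill holes** — the binarized edge of a colony is a closed
   (or nearly closed) ring; morphological closing bridges one-pixel gaps
   and hole filling turns rings into solid objects.
7. **Maximum / close / fill / Minimum** — a second chance for objects
   whose ring has larger gaps: dilating by $r_{\max}$ pulls gap flanks
   together, closing and filling captures the interior, eroding by
   $r_{\min}$ returns the object to size. Because the binarized edge ring
   sits *outside* the true boundary by one or two pixels, $r_{\min}$ is
   usually chosen 1–2 px larger than $r_{\max}$; the exact values depend
   on image resolution and object scale and are per-class tunables.
8. **Remove outliers** — a median-deviation filter: each pixel deviating
   from its disk-neighbourhood median by more than a threshold (in the
   chosen polarity) is replaced by that median. On the binary image this
   deletes any foreground blob smaller than about half the neighbourhood
   disk. Caution: it equally *erodes the boundary* of true objects whose
   radius is below ~1.3× the filter radius, so the radius must stay
   below about half the smallest object radius.
9. **Watershed** — touching objects are split on the inverted Euclidean
   distance map (below).
10. **Measure + filter** — connected components (8-connectivity) are
    measured and filtered by calibrated size, circularity and border
    contact.

Stages can be disabled per run (`toggleStage()`): skip the watershed for
non-circular cells whose processes would be cut off; skip hole filling
when measuring open networks such as endothelial tubes, where filling
would annex the gaps between branches.

### Automatic thresholding

Three estimators are available in `makeBinary()`:

* **IsoData** (default): iterative intermeans — the threshold converges
  to the midpoint of the class means below and above it. Reliable when
  foreground and background intensities form two populations, as in the
  edge image of a high-contrast scene.
* **Otsu** (via EBImage): maximizes inter-class variance; behaves much
  like IsoData on these histograms.
* **Triangle**: the geometric rule for strongly skewed unimodal
  histograms — a line from the histogram peak to the end of the longer
  tail, threshold at the bin of maximal distance below it. This is the
  right tool for edge-magnitude images whose edge strengths span a wide
  range: intermeans midpoints between *weak and strong edges* and can
  discard faint objects wholesale, whereas the triangle rule keys the
  threshold off the *background/noise* population. The triangle rule
  needs a visible noise toe in the histogram; on a noise-free synthetic
  image it degenerates (the background collapses into a single bin) and
  IsoData is the better default.

### Watershed splitting

`binaryWatershed()` implements marker-based splitting on the exact
Euclidean distance map: seeds are the regional maxima, with maxima merged
when their peaks differ by at most `tolerance` along a connecting path
(candidates are visited in decreasing height order; a flood that reaches
ground claimed by a higher maximum yields no seed). Flooding then
proceeds from the seed plateaus in decreasing distance order with ties
broken by raster index, so results are bit-reproducible. Where two floods
meet, a one-pixel divide line becomes background. An object containing a
single seed is returned unchanged.

The default tolerance of 0.5 suppresses double seeding on the
near-integer plateaus of discrete distance maps. The method is reliable
only for convex, roughly circular/elliptical objects: an elongated
object's distance-map ridge carries several spurious maxima, and
moderately deep saddles will split it. This is a documented limitation,
not a defect to be patched — for elongated cells, disable the stage.

### Measurement conventions

Area is the pixel count times calibration². Perimeter is the Freeman
chain-code length of the outer contour (orthogonal step 1, diagonal
$\sqrt2$) — a 10×10 square measures exactly 36. This estimator
overestimates *smooth* contours by ≈5% asymptotically, so the
circularity $\min(1,\,4\pi A/P^2)$ of a large digital disk plateaus near
0.9 rather than reaching 1; circularity filters in the presets
(0.2–1) are far from this regime. Holes do not contribute to the
perimeter (pipelines fill holes before measuring). A single-pixel object
has zero chain length and counts as circular. Intensity statistics are
taken from a redirect image — normally the unprocessed original — so
measurements reflect raw data, not filtered values.

## Presets and per-class configurations

`pipelinePreset()` returns the reference parameter sets for the three
assay classes (tumorsphere: background radius 80,
blur σ 2, Maximum 2 / Minimum 3, Remove Outliers radius 12, particles
50–∞ µm², circularity 0.2–1; bacterial: no background subtraction, two
Remove Outliers passes of radius 2 then blur σ 1, particles 2–∞ px²;
clonogenic: background 50, blur σ 0.5, Remove Outliers 2, Maximum 1 /
Minimum 4, Remove Outliers 5, particles 50–∞ px²), plus a
fluorescent-nuclei recipe and a thresholding baseline (background
subtraction + global threshold + watershed) for comparison. Two notes on
these sets:

* The bacterial class needs *two* outlier-removal passes with different
  thresholds (50, then 25): the first deletes the near-saturated core of
  white scratch marks, the second their sub-threshold anti-aliased
  flanks, which would otherwise be amplified by the closing steps into
  strings of false colonies.
* The contrast-enhancement step (“0.2 % saturated”) is retained in the
  presets as a linear rescale mapping the 0.1 % and 99.9 % quantiles to
  the depth range. Beware that on low-dynamic-range images this rescale
  multiplies sensor noise along with signal; in the original
  interactive tool the same command alters only the *display* range
  unless normalization is requested, which is why the reference sets
  work on faint images where a data rescale would not.

These numbers were determined by trial and error *for particular
instruments and image classes*; the method's doctrine is that each image class gets its own
determination (4–8 representative images, `sweepParameters()` automates
the grid search against a reference table). `scenarioConfig()` records
the configurations determined once, by that same procedure, for the
synthetic scenarios below. The tumorsphere-like configuration differs
from the preset deliberately: no data-space contrast rescale, triangle
threshold (contrast floor 15/255 puts the faintest edge ridges below the
intermeans threshold), blur σ 1.5, Maximum 2 / Minimum 4, denoising
radius 5 (objects down to 10 px radius must survive the median filter).

## The synthetic scene generator

`generateScene()` renders what the real assays look like to the
pipeline, with analytic ground truth: anti-aliased ellipses (edge
softness 1 px, true area $\pi ab$) over a configurable background with a
linear illumination gradient and/or radial vignette, iid Gaussian sensor
noise, small speck artifacts (the generator gives them the majority
object polarity, emulating cell debris), and near-saturated hairline
scratch lines (white, 0.7–1.2 px wide — what scratch marks look like in
plate photographs, and what a radius-2 median pass can erase). Touching
pairs are rendered as unions with no intensity ridge, the hardest case
for the watershed. Generation is deterministic in the scene seed; the
truth table does not depend on the noise realization.

The named scenarios fix the study conditions: `tumorsphere_like`
(640×640, twelve dark near-circular ellipses with semi-axes 10–60 px,
contrast 15–40 on a background of 200, 10 % linear gradient, noise σ 2,
2 µm/px), `bacterial_like` (256×256, 22 bright disks of radius 2–6 px,
five scratches, ten specks), `clonogenic_like` (384×384, forty dark
disks of radius 4–12 px), `touching_pairs` (one fused equal-radius pair
at centre distance 1.2–1.6 r), and `artifact_stress` (eight true disks
plus 520 sub-threshold specks and five scratches). Problem sizes were
chosen so a full scenario analysis runs in seconds on one core while
objects remain large enough for meaningful area statistics.

What the generator does **not** emulate: focus blur, Nomarski relief
shading, spatially correlated noise, intensity texture inside colonies,
and plate rims. Passing on these scenes therefore demonstrates the
pipeline's contracts (detection at low contrast, illumination
invariance, splitting, artifact rejection, determinism) — it does not
guarantee parameter transfer to any particular microscope; per-class
parameter determination on real images remains part of the method.

## Evaluation protocol

`matchObjects()` implements the standard comparison rules: references
are processed in decreasing area order, each taking the largest-area
unassigned detection whose centroid lies within the reference's matching
radius (`max(radius_px, maxCentroidDistance)` — the original matching
was done by eye, so an explicit distance rule is a necessary
operationalization). Fragmented objects match by their largest fragment,
the rest becoming extra objects numbered after the last reference id;
an unsplit fusion matches the larger reference, the smaller one counting
as undetected. `agreement()` then fits detected measure on reference
measure by ordinary least squares (slope, intercept, R², mean absolute
deviation); `replicateAverage()` averages repeated runs per object — for
this fully deterministic pipeline the standard errors are exactly zero,
which is itself a tested property.

On `tumorsphere_like` scenes the full chain recovers all twelve objects
across generator seeds with per-object area errors within 15 %, slope
within [0.9, 1.1] and R² above 0.98; fused pairs split in at least 18 of
20 scenes; `artifact_stress` scenes yield zero false positives with all
true objects retained. These are the quantities `scripts/acceptance.R`
recomputes.

## Numerical choices and degenerate inputs

* All window operations use edge replication (clamped indices), keeping
  border-object measurements stable; closing remains extensive under
  this policy.
* Digital disk of radius $r$ = offsets with $|d| \le r+0.5$ (rank-filter
  convention); disk neighbourhoods always contain an odd pixel count, so
  binary medians are exact, and two-valued images take an exact counting
  fast path.
* The rolling ball is computed exactly (no shrink-and-interpolate
  approximation); the Gaussian kernel is truncated at $3\sigma$ and
  renormalized; IsoData iterates on the raw values to a $10^{-7}$
  fixpoint; a constant image binarizes to all-background.
* Seed finding and flooding order ties break on (value, column-major
  index); labels are numbered by raster scan of first pixels. Identical
  image + configuration therefore reproduce bit-identical masks, label
  maps and CSVs.
* 8-bit and 16-bit data are processed in double precision throughout and
  quantized only on export; `maxValue` records the depth range used by
  clipping and rescaling stages.
* Pipelines must contain exactly one binarization stage; binary-domain
  stages cannot precede it and grayscale-only stages cannot follow it —
  violations are rejected before any computation.

## Known limitations

Non-circular objects are oversegmented by the watershed (skip the stage
and plate at low density instead). Objects wider than twice the rolling
ball radius lose interior amplitude, which is harmless for detection but
biases *intensity* measurements of very large objects. Faint debris at
colony-like contrast and size is indistinguishable from small colonies
by construction; the bacterial scenarios therefore report residual
artifact-borne extras rather than pretending to remove them. The
chain-code perimeter overestimates smooth boundaries by ≈5 %, a bias
shared by the comparison protocol on both sides of the regression.
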