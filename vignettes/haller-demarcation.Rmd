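---
title: "Demarcating Haller's layer in choroidal OCT B-scans: methods and design"
author: "hallerseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating Haller's layer in choroidal OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallerseg)
```

## The problem

The choroid, the vascular tissue between retina and sclera, is organized
in three sublayers: the choriocapillaris (finest vessels, adjoining
Bruch's membrane), Sattler's layer (medium calibers), and Haller's layer
(the largest vessels, adjoining the choroid–sclera interface, CSI).
Several diseases are thought to affect specific sublayers, so a
quantitative boundary between Haller's and Sattler's layers in
swept-source OCT B-scans is clinically useful — but manual tracing is
tedious and irreproducible, because the sublayers are not separated by
an intensity edge. Gradient-based layer segmentation, which works well
for retinal layers, therefore does not apply; the boundary must be
inferred from vessel *caliber*.

`hallerseg` implements an automated demarcation pipeline built on that
idea: binarize the choroid into lumen and stroma, separate the packed
vessel cross-sections, classify the large ones, and fit a smooth curve
through their innermost points. The package assumes the choroid band
itself (the inner boundary CIB and outer boundary COB, the latter
coinciding with the CSI) is already known — dedicated choroid
segmentation methods solve that problem with high accuracy, and the
curves are accepted as CSV input. A crude profile-threshold fallback
detector is included only so the tool runs end to end without them.

## Pipeline

Given a normalized scan $I \in [0,1]^{R \times C}$ (rows = axial depth,
row 1 innermost):

1. **Wiener denoising.** Adaptive local Wiener filter with a $5 \times 5$
   window: with local mean $\mu$, local variance $v$, and noise floor
   $\nu$ (the image-wide mean of local variances),
   $\hat I = \mu + \frac{\max(0, v - \nu)}{\max(v, \nu)}(I - \mu)$.
   Flat speckle collapses to its mean while strong edges (where
   $v \gg \nu$) survive. Borders are edge-replicated.
2. **Adaptive histogram equalization** over an $8\times8$ tile grid
   with bilinear interpolation between tile mappings, to lift the low
   lumen/stroma contrast of the deep choroid. The clip limit is
   expressed as a multiple of the uniform histogram level
   (`claheClip`, default 1.2; see *Calibrated constants*).
3. **Exponential enhancement and binarization.** Pointwise power law
   $I \mapsto I^\gamma$ (default $\gamma = 2$) rescaled to $[0,1]$,
   which darkens lumens relative to stroma and widens the bimodal gap,
   followed by a global Otsu threshold on a 256-level quantization.
   The dark class becomes the lumen-foreground mask (the complement
   that makes vessels white is folded into `thresholdBinarize()`).
4. **Band restriction.** Everything outside $[\mathrm{CIB}(c),
   \mathrm{COB}(c)]$ is cleared. Curves stay fractional; rows are
   quantized half-up only when indexing pixels.
5. **Morphological opening, then closing**, both with a $5\times5$
   square. The opening debrides speckle-induced salt residue and thin
   protrusions *before* the closing can weld them onto vessels; the
   closing then fills intra-vessel gaps and smooths contours. The
   opening is this package's addition to the classical
   binarize–close–watershed chain: closing alone is extensive and
   cannot remove foreground residue, and on speckled data the residue
   otherwise corrupts the large-vessel statistics (see *Why the
   opening matters*).
6. **Watershed separation.** The Euclidean distance transform $D$ of
   the lumen mask is used as a relief (flooded from its maxima, i.e.
   the watershed of $-D$); basins whose dynamic is below $h$
   (`hminimaDepth`, default 2 px) are merged first — the
   extended-minima criterion that prevents the over-segmentation a raw
   distance watershed produces. Labels are the 8-connected components
   of the mask minus the watershed ridges; components under
   `minVesselPx` (default 5 px) are dropped as residue. Vessels
   clipped by the lateral image borders are retained.
7. **Large-vessel classification.** Step 1: every vessel whose minimum
   vertical distance to the COB is at most `csiProximityPx` (default
   5 px) belongs to Haller's layer. Step 2: of the remaining vessels,
   those with area strictly greater than the median area of the step-1
   set are added. The median over an even count is the mean of the
   middle pair. No absolute caliber threshold exists for "large", so
   the rule is relative by design; the median makes it robust to
   individual mis-segmentations.
8. **Two-stage demarcation.** The innermost (minimum-row) pixel of each
   large vessel — ties broken toward the smaller column — is an anchor.
   Piecewise-linear interpolation through the anchors (constant
   extension beyond the outermost anchors) gives the initial estimate;
   robust locally weighted linear regression (LOWESS: tricube distance
   weights, bisquare robustness reweighting, 3 robustness iterations,
   span one fifth of the scan width) smooths it. The curve is clamped
   into $[\mathrm{CIB}, \mathrm{COB}]$ column-wise. If no large vessel
   was found the boundary degenerates to the COB (zero-thickness
   Haller layer) and is flagged.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `wienerKernel` | 5 | px | Wiener window; larger = smoother, blurrier edges |
| `claheTiles` | 8 | tiles/side | equalization granularity |
| `claheClip` | 1.2 | × uniform level | contrast amplification cap (calibrated) |
| `exponent` | 2 | — | power-law enhancement strength |
| `openingSe` | 5 | px | residue debridement element |
| `closingSe` | 5 | px | gap-filling element |
| `hminimaDepth` | 2 | DT px | basin-merging depth (calibrated) |
| `minVesselPx` | 5 | px | smallest component kept |
| `csiProximityPx` | 5 | px | CSI adjacency band |
| `smoothWindowFrac` | 1/5 | of width | LOWESS span |
| `axialScaleUm` | 2.6 | µm/px | axial pixel pitch for µm reporting |

The axial scale converts pixel differences into micrometres for the
absolute-difference statistic; swept-source devices differ and the
value should be set from the device calibration — 2.6 µm/px is a
typical swept-source figure, not a universal constant.

### Calibrated constants

Two constants are not dictated by the algorithm and were fixed by
calibration on synthetic phantoms (seeds disjoint from any test seed
used elsewhere): `hminimaDepth = 2` is the smallest depth at which
overlapping equal disks are still split while single disks are never
fragmented, and `claheClip = 1.2` is the strongest clip at which the
equalization stops amplifying homogeneous-stroma speckle into threshold
noise while still stretching genuine lumen/stroma contrast. Both remain
exposed in `pipelineConfig()`.

### Why the opening matters

Under multiplicative speckle the Otsu threshold inevitably leaves a few
percent of stroma pixels in the dark class, scattered as small salt
clusters. Closing is extensive — it can only grow foreground — so those
clusters survive it and, worse, get welded onto genuine vessels and
each other, producing junk components that (a) enter the CSI-adjacent
set and distort the median-area threshold and (b) get selected by the
area rule and drag the boundary toward the CIB. An opening with the
same $5\times5$ element, applied before the closing, removes any
component or protrusion that cannot contain the element while leaving
every vessel wider than 5 px intact (the smallest Sattler vessels the
classification can use are ~10 px across). On speckled phantoms this
single step moves the mean boundary recovery error from tens of pixels
to under one pixel; the noise-free path is unaffected.

## The synthetic phantom

`generatePhantom()` builds a B-scan-like raster with complete ground
truth, so every stage is testable without clinical data:

* smooth random CIB/COB curves (two low-frequency sinusoids, a few px
  amplitude) around a 40 px deep, 150 px thick band;
* elliptical vessel lumens (intensity 0.15) on bright stroma (0.65) in
  three strata mirroring the anatomy — choriocapillaris (semi-axes
  1–3 px) in the inner band, Sattler (5–10 px) mid-band, Haller
  (12–20 px) with the outer edge within ~0.5–2.5 px of the COB, so the
  planted large vessels genuinely adjoin the CSI;
* at least 6 px clearance between vessels, so the $5\times5$ closing
  cannot merge planted structures into artificial giants;
* multiplicative gamma speckle with mean 1 and shape `speckleLooks`
  (default 4, i.e. 50 % intensity CV — a harsh, non-averaged
  acquisition), disableable via `noiseFree`;
* a ground-truth Haller boundary built by applying the *same* two-stage
  interpolation to the true innermost points of the planted large
  vessels. Recovery error therefore isolates segmentation quality from
  curve-construction convention.

Everything is deterministic per seed; `degradePhantom()` additionally
compresses the lumen/stroma gap before re-applying the stored speckle
field, as a low-contrast stress fixture.

What the phantom does **not** emulate: retinal layering above the
choroid (the region above the CIB is a uniform moderate level),
depth-dependent signal attenuation, spatially correlated speckle, motion
or vignetting artifacts, and pathological morphology. Passing the
recovery suite therefore shows the chain is correct and robust to heavy
uncorrelated speckle — it does not certify clinical accuracy, which the
agreement metrics against manual markings are for.

The recovery suite runs the full pipeline on twenty 512×256 phantoms
with 3–6 large, 6–10 medium and 20–40 small vessels under 4-look
speckle, and on noise-free phantoms; these sizes keep the whole test
suite under a minute while still exercising dozens of vessels per
stratum.

## Agreement metrics

For two Haller boundaries $a, b$ (and band curves for region
construction):

* **AD** — mean absolute difference, $\mathrm{mean}_c |a(c) - b(c)|$
  × axial scale, in µm;
* **CC** — Pearson correlation of the row vectors (undefined for a
  constant curve; returned as `NA` with a warning);
* **DC** — Dice coefficient $2|A \cap B| / (|A| + |B|)$ of the two
  Haller-layer regions, each rasterized as
  $\{(r, c) : \mathrm{haller}(c) \le r \le \mathrm{COB}(c)\}$. The
  Haller region (boundary to COB) is this package's choice of region;
  it is isolated in `diceLayers()` so an alternative region is one
  function away. Two empty regions give DC = 1 with a warning.

`summarizeCohort()` reports mean, sample SD ($n-1$), min, max and
CV = SD/mean per metric for both comparisons (automated vs the manual
reference — the average of two manual markings — and the two manual
markings against each other), plus quotient measures:
$\mathrm{QCV} = \mathrm{CV}_{auto}/\mathrm{CV}_{manual}$ for every
metric, and $\mathrm{QM} = \mathrm{mean}_{auto}/\mathrm{mean}_{manual}$
for error metrics but
$(100 - \mathrm{mean}_{auto})/(100 - \mathrm{mean}_{manual})$ for
similarity metrics expressed as percentages. The complement scale makes
"how far from perfect agreement" the compared quantity, so a quotient
near 1 means parity with manual grading for every metric kind. These
definitions reproduce, to the printed two decimals, all six quotient
values of the published 50-eye benchmark summary shipped in
`inst/extdata/benchmark_cohort_stats.csv` (the acceptance suite checks
this).

## Numerical choices and degenerate inputs

* Coordinates are 1-based in memory; the CSV dialect on disk is
  0-based with fractional rows (`column,row` header), so smoothing
  output is never quantized by I/O. Round trips are lossless to 1e-9.
* Boundary rows are rounded half-up (`floor(x + 0.5)`) only at
  mask-indexing time.
* Otsu's minimizer can be a plateau when the histogram has an empty
  gap; any threshold in the gap induces the same partition, and tests
  compare the achieved intra-class-variance objective rather than the
  raw threshold.
* Vessel components use 8-connectivity; watershed regions are split by
  the (component × watershed label) pair, so ridge lines act as
  separators without being stored.
* Even-count medians are the mean of the middle pair; the area rule is
  a strict inequality — both pinned by tests.
* Extension beyond the outermost anchors is constant, not linear:
  extrapolated slopes from close anchor pairs near borders are
  unstable, constants are not.
* Degenerate cases are defined, not fatal: constant images pass
  through equalization unchanged (warning), produce an all-stroma
  mask (warning), and flat default fallback boundaries; an empty
  large-vessel set yields the COB as boundary with a flag; empty
  regions give DC = 1 with a warning; a constant curve has undefined
  CC (`NA`).
* All generator randomness is seeded and the caller's RNG state is
  restored; regeneration is bit-identical.

## Known limitations

* Healthy-eye morphology is assumed: one contiguous choroid band and
  large vessels that actually reach the CSI. Pathologies that disrupt
  the band (large pigment epithelial detachments, tumors) will need
  adapted rules.
* The demarcation is per-B-scan; no longitudinal (cross-scan)
  smoothness is enforced.
* The fallback boundary detector is plumbing with phantom-grade
  accuracy only; clinical use should supply CIB/COB from a dedicated
  choroid segmentation method.
* Sattler vs choriocapillaris are not sub-classified; the rule set
  only separates large from the rest.
* The Otsu threshold is global. Strong axial attenuation gradients in
  real scans are partially compensated by the tiled equalization, but
  a locally adaptive threshold may be needed for low-quality volumes.
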