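# hallerseg

Automated demarcation of the boundary between **Haller's and Sattler's
layers** of the choroid in single swept-source OCT B-scans, with
agreement metrics for validation against manual markings and a seeded
synthetic phantom generator for testing without clinical data.

## The problem

The choroid consists of the choriocapillaris (innermost, finest
vessels), Sattler's layer (medium calibers) and Haller's layer (the
largest vessels, adjoining the choroid–sclera interface, CSI). Because
the sublayers are not separated by an intensity edge, gradient-based
layer segmentation — the workhorse for retinal layers — does not apply;
the Haller/Sattler boundary must be inferred from vessel caliber. This
package is for image-analysis and ophthalmic-research groups who have
B-scans with known choroid boundaries (CIB/COB) and need a reproducible,
quantitative Haller boundary per scan.

## The method

For a normalized scan `I ∈ [0,1]^{R×C}` with band curves CIB(c) ≤ COB(c):

1. adaptive 5×5 Wiener denoising,
   `Î = μ + max(0, v − ν)/max(v, ν) · (I − μ)` with ν the image-wide
   mean local variance, then 8×8-tile adaptive histogram equalization;
2. power-law enhancement `I ↦ I²` (rescaled) and a global Otsu
   threshold; the dark class is the vessel-lumen mask;
3. restriction to the band, a 5×5 opening (speckle debridement) and a
   5×5 closing;
4. watershed of the negated Euclidean distance transform with
   extended-minima merging (depth `h = 2` px) to split touching
   vessels into 8-connected cross-sections;
5. large-vessel classification: every vessel within 5 px (vertical) of
   the COB, plus any remaining vessel with area strictly greater than
   the median area of that CSI-adjacent set;
6. two-stage demarcation: piecewise-linear interpolation through the
   innermost pixel of each large vessel, then robust LOWESS (tricube ×
   bisquare, span = width/5), clamped into `[CIB, COB]`.

Agreement between two demarcations is scored by mean absolute
difference (AD, µm), Pearson correlation of the boundary rows (CC) and
the Dice coefficient (DC) of the Haller-layer regions; cohort summaries
add mean/SD/CV and the quotient measures QM and QCV against
intra-observer repeatability (QM on the complement scale
`(100 − m_auto)/(100 − m_manual)` for similarity metrics, so 1 always
means parity with manual grading).

## Worked example

Generate a speckled phantom with known truth, run the pipeline, and
score it:

```r
library(hallerseg)

ph  <- generatePhantom(phantomSpec(seed = 42))
seg <- segmentHaller(ph@scan, ph@cib, ph@cob)
seg
#> HallerSegmentation:
#>   HallerBoundary: 4 anchors, rows 146.34..160.36
#>   LargeVesselSet: 4 large (4 CSI-adjacent + 0 by area > median 905.5 px)

scanAgreement(hallerCurve(seg), ph@hallerTruth, ph@cib, ph@cob)
#>      ad_um        cc        dc
#> 0.07172004 0.9998976 0.9996502

hallerThicknessUm(hallerCurve(seg), ph@cob)
#> [1] 91.68747
```

All four planted Haller vessels were found CSI-adjacent (median
cross-section 905.5 px², so the area rule added none), and the
recovered boundary agrees with the planted truth to 0.07 µm mean
absolute difference (at 2.6 µm/px), correlation 0.9999 and layer Dice
0.9997. The mean Haller thickness of this phantom is ≈ 92 µm.

On real data, supply the scan and boundary CSVs instead:

```r
scan <- readBScan("scan.png")
cib  <- readBoundaryCsv("cib.csv", ncol(scanPixels(scan)), "CIB")
cob  <- readBoundaryCsv("cob.csv", ncol(scanPixels(scan)), "COB")
seg  <- segmentHaller(scan, cib, cob)
writeBoundaryCsv(hallerCurve(seg), "haller.csv")
```

or use the CLI (`inst/scripts/hallerseg`):

```sh
hallerseg segment --image scan.png --cib cib.csv --cob cob.csv --out-dir out --debug-stages
hallerseg evaluate --auto a1.csv,a2.csv --m1 m1a.csv,m2a.csv --m2 m1b.csv,m2b.csv \
                   --cib c1.csv,c2.csv --cob o1.csv,o2.csv --out-dir report
hallerseg synth --seed 7 --out-dir phantom
```

`segment` writes the Haller boundary CSV, per-vessel statistics and a
JSON run manifest (plus ten per-stage debug images with
`--debug-stages`); `evaluate` builds the manual reference (average of
two markings) per scan and emits the cohort summary with quotient
measures; `synth` writes a phantom with its full ground truth.

## Documentation

The methods vignette (`vignettes/haller-demarcation.Rmd`) describes the
model, every tunable parameter with its default and rationale, the
phantom's design and its limits, numerical conventions and degenerate
cases.
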