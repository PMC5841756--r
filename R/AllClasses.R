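#' @import methods
NULL

#' OCT B-scan raster
#'
#' A single grayscale OCT B-scan. Rows index axial depth (row 1 is the
#' innermost, vitreous-side row), columns index lateral position. Pixel
#' values are normalized intensities in \[0, 1\].
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\];
#'   at least 32 rows and 32 columns.
#' @slot axialScaleUm axial pixel pitch in micrometres per pixel (> 0).
#' @slot lateralScaleUm lateral pixel pitch in micrometres per pixel (> 0).
#' @slot sourcePath provenance string (file path or generator tag).
#'
#' @seealso [readBScan()], [generatePhantom()]
#' @export
setClass("BScan",
  representation(
    pixels = "matrix",
    axialScaleUm = "numeric",
    lateralScaleUm = "numeric",
    sourcePath = "character"
  )
)

setValidity("BScan", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 32L || ncol(p) < 32L)
    return("B-scan must be at least 32 x 32 pixels")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("pixel values must lie in [0, 1]")
  if (length(object@axialScaleUm) != 1L || object@axialScaleUm <= 0)
    return("axialScaleUm must be a single positive number")
  if (length(object@lateralScaleUm) != 1L || object@lateralScaleUm <= 0)
    return("lateralScaleUm must be a single positive number")
  TRUE
})

#' Preprocessed B-scan
#'
#' A [BScan-class] after denoising/contrast enhancement, carrying the
#' ordered list of operators applied.
#'
#' @slot provenance character vector of applied operator descriptions,
#'   in application order.
#' @export
setClass("PreprocessedBScan", contains = "BScan",
  representation(provenance = "character"))

#' Boundary curve
#'
#' One axial (row) position per image column, fractional pixels allowed.
#' Rows are 1-based in memory; the CSV interchange format is 0-based
#' (see [readBoundaryCsv()]).
#'
#' @slot rows numeric vector, one row position per column.
#' @slot kind one of \code{"CIB"}, \code{"COB"}, \code{"HALLER"},
#'   \code{"MANUAL"}.
#' @export
setClass("BoundaryCurve",
  representation(rows = "numeric", kind = "character"))

.curveKinds <- c("CIB", "COB", "HALLER", "MANUAL")

setValidity("BoundaryCurve", function(object) {
  if (length(object@rows) < 1L) return("curve must span at least one column")
  if (anyNA(object@rows) || any(!is.finite(object@rows)))
    return("curve rows must be finite")
  if (any(object@rows < 1)) return("curve rows must be >= 1 (1-based)")
  if (length(object@kind) != 1L || !(object@kind %in% .curveKinds))
    return(sprintf("kind must be one of %s", paste(.curveKinds, collapse = ", ")))
  TRUE
})

#' Binarized choroid layer (BCL)
#'
#' Binary raster restricted to the choroid band between the choroid inner
#' boundary (CIB) and choroid outer boundary (COB). Polarity is fixed:
#' \code{TRUE} marks vessel lumen, \code{FALSE} stroma or outside-band.
#'
#' @slot mask logical matrix, same shape as the source scan.
#' @slot cib,cob [BoundaryCurve-class] objects delimiting the band.
#' @export
setClass("BinarizedChoroid",
  representation(mask = "matrix", cib = "BoundaryCurve", cob = "BoundaryCurve"))

setValidity("BinarizedChoroid", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  w <- ncol(object@mask)
  if (length(object@cib@rows) != w || length(object@cob@rows) != w)
    return("boundary curves must span all mask columns")
  if (any(object@cib@rows > object@cob@rows))
    return("CIB must lie on or above COB at every column")
  # band restriction: nothing outside [cib, cob]
  ri <- .roundHalfUp(object@cib@rows)
  ro <- .roundHalfUp(object@cob@rows)
  rr <- row(object@mask)
  out <- sweep(rr, 2L, ri, "<") | sweep(rr, 2L, ro, ">")
  if (any(object@mask & out))
    return("mask has lumen pixels outside the [CIB, COB] band")
  TRUE
})

#' Labeled vessel cross-sections
#'
#' Connected vessel cross-sections after watershed separation. Label 0 is
#' background; labels 1..n are 8-connected components. Per-label summary
#' statistics are kept alongside.
#'
#' @slot labels integer matrix of vessel ids (0 = background).
#' @slot stats data.frame with one row per label: \code{label},
#'   \code{area_px}, \code{innermost_row}, \code{innermost_col}
#'   (minimum-row pixel, ties broken by minimum column),
#'   \code{min_dist_to_cob_px} (minimum vertical distance to the COB).
#' @export
setClass("VesselLabelMap",
  representation(labels = "matrix", stats = "data.frame"))

setValidity("VesselLabelMap", function(object) {
  L <- object@labels
  if (!is.integer(L)) return("labels must be an integer matrix")
  n <- nrow(object@stats)
  ids <- sort(unique(L[L > 0L]))
  if (!identical(as.integer(ids), seq_len(n)))
    return("labels must be consecutive 1..n matching stats rows")
  if (n > 0L && !identical(sum(object@stats$area_px), sum(L > 0L)))
    return("sum of per-label areas must equal number of labeled pixels")
  TRUE
})

#' Large-vessel classification result
#'
#' The subset of vessel labels classified as large (Haller's layer)
#' vessels: the union of the CSI-proximity step and the median-area step.
#' The two id sets are disjoint by construction.
#'
#' @slot labelIds all large-vessel ids (union of the two steps).
#' @slot csiAdjacentIds ids within the proximity threshold of the COB.
#' @slot areaSelectedIds remaining ids with area strictly greater than
#'   the median CSI-adjacent area.
#' @slot medianAreaPx the median area threshold used (NA when no
#'   CSI-adjacent vessel exists).
#' @export
setClass("LargeVesselSet",
  representation(labelIds = "integer", csiAdjacentIds = "integer",
                 areaSelectedIds = "integer", medianAreaPx = "numeric"))

setValidity("LargeVesselSet", function(object) {
  if (length(intersect(object@csiAdjacentIds, object@areaSelectedIds)) > 0L)
    return("CSI-adjacent and area-selected id sets must be disjoint")
  if (!setequal(object@labelIds,
                union(object@csiAdjacentIds, object@areaSelectedIds)))
    return("labelIds must be the union of the two selection steps")
  TRUE
})

#' Demarcated Haller boundary
#'
#' The smooth boundary between Haller's and Sattler's layers, produced by
#' two-stage interpolation through the innermost points of the large
#' vessels, clamped into the choroid band.
#'
#' @slot curve a [BoundaryCurve-class] of kind \code{"HALLER"}.
#' @slot anchors numeric matrix with columns \code{row}, \code{col}: the
#'   innermost pixel of each large vessel, sorted by column.
#' @slot fallbackUsed logical; \code{TRUE} when no large vessel was found
#'   and the curve fell back to the COB (degenerate Haller layer).
#' @export
setClass("HallerBoundary",
  representation(curve = "BoundaryCurve", anchors = "matrix",
                 fallbackUsed = "logical"))

#' Pipeline configuration
#'
#' Tunable parameters of the demarcation pipeline with their defaults.
#' Construct with [pipelineConfig()].
#'
#' @slot wienerKernel odd Wiener window size (pixels, default 5).
#' @slot claheTiles tile grid count per side for adaptive histogram
#'   equalization (default 8).
#' @slot claheClip contrast clip limit as a multiple of the uniform
#'   histogram bin height (default 1.2, calibrated on phantoms).
#' @slot exponent power-law enhancement exponent (default 2).
#' @slot openingSe square structuring-element side for the speckle
#'   debridement opening (default 5).
#' @slot closingSe square structuring-element side for morphological
#'   closing (default 5).
#' @slot hminimaDepth extended-minima depth h in distance-transform pixels
#'   (default 2).
#' @slot minVesselPx components smaller than this (pixels) are discarded
#'   as binarization residue (default 5).
#' @slot csiProximityPx CSI adjacency threshold in pixels (default 5).
#' @slot smoothWindowFrac smoothing span as a fraction of scan width
#'   (default 1/5).
#' @slot axialScaleUm axial pixel pitch in micrometres (default 2.6).
#' @slot lateralScaleUm lateral pixel pitch in micrometres (default 11.7).
#' @slot fallbackDepthPx choroid depth assumed by the fallback boundary
#'   detector when no gradient evidence exists (default 150).
#' @export
setClass("PipelineConfig",
  representation(
    wienerKernel = "integer", claheTiles = "integer", claheClip = "numeric",
    exponent = "numeric", openingSe = "integer",
    closingSe = "integer", hminimaDepth = "numeric",
    minVesselPx = "integer", csiProximityPx = "integer",
    smoothWindowFrac = "numeric", axialScaleUm = "numeric",
    lateralScaleUm = "numeric", fallbackDepthPx = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  if (object@wienerKernel < 3L || object@wienerKernel %% 2L == 0L)
    return("wienerKernel must be odd and >= 3")
  if (object@claheTiles < 1L) return("claheTiles must be >= 1")
  if (object@claheClip <= 0) return("claheClip must be > 0")
  if (object@exponent <= 0) return("exponent must be > 0")
  if (object@openingSe < 1L) return("openingSe must be >= 1")
  if (object@closingSe < 1L) return("closingSe must be >= 1")
  if (object@hminimaDepth <= 0) return("hminimaDepth must be > 0")
  if (object@minVesselPx < 0L) return("minVesselPx must be >= 0")
  if (object@csiProximityPx < 0L) return("csiProximityPx must be >= 0")
  if (object@smoothWindowFrac <= 0 || object@smoothWindowFrac > 1)
    return("smoothWindowFrac must be in (0, 1]")
  if (object@axialScaleUm <= 0) return("axialScaleUm must be > 0")
  if (object@lateralScaleUm <= 0) return("lateralScaleUm must be > 0")
  if (object@fallbackDepthPx < 1L) return("fallbackDepthPx must be >= 1")
  TRUE
})

#' Synthetic phantom specification
#'
#' Parameters of the synthetic choroid phantom: a stromal band between two
#' smooth boundary curves, dark elliptical vessel lumens in three
#' anatomical strata (choriocapillaris near the CIB, Sattler mid-band,
#' Haller adjoining the COB with the largest calibers), and multiplicative
#' L-look gamma speckle. Construct with [phantomSpec()].
#'
#' @slot width,height phantom size in pixels (columns, rows).
#' @slot cibDepth mean CIB depth from the top of the image (pixels).
#' @slot choroidThickness mean band thickness (pixels).
#' @slot nLarge,nMedium,nSmall vessel counts per stratum.
#' @slot largeRadius,mediumRadius,smallRadius semi-axis ranges per stratum
#'   (pixels); strictly ordered small < medium < large.
#' @slot stromaLevel,lumenLevel noise-free intensities in \[0, 1\].
#' @slot speckleLooks gamma speckle shape parameter L (mean-1
#'   multiplicative noise; larger L = less noise).
#' @slot noiseFree disable speckle entirely (the L -> Inf limit).
#' @slot seed integer RNG seed; regeneration is bit-identical.
#' @export
setClass("PhantomSpec",
  representation(
    width = "integer", height = "integer",
    cibDepth = "numeric", choroidThickness = "numeric",
    nLarge = "integer", nMedium = "integer", nSmall = "integer",
    largeRadius = "numeric", mediumRadius = "numeric", smallRadius = "numeric",
    stromaLevel = "numeric", lumenLevel = "numeric",
    speckleLooks = "numeric", noiseFree = "logical", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@width < 64L || object@height < 64L)
    return("phantom must be at least 64 x 64")
  r <- rbind(object@smallRadius, object@mediumRadius, object@largeRadius)
  if (any(r[, 1] > r[, 2]) || any(r <= 0))
    return("radius ranges must be positive with min <= max")
  if (!(object@smallRadius[2] < object@mediumRadius[1] &&
        object@mediumRadius[2] < object@largeRadius[1]))
    return("radius strata must be strictly ordered: small < medium < large")
  if (object@lumenLevel >= object@stromaLevel)
    return("lumenLevel must be darker than stromaLevel")
  if (min(object@lumenLevel, object@stromaLevel) < 0 ||
      max(object@lumenLevel, object@stromaLevel) > 1)
    return("intensity levels must lie in [0, 1]")
  if (object@speckleLooks <= 0) return("speckleLooks must be > 0")
  if (object@cibDepth + object@choroidThickness > object@height - 20)
    return("choroid band does not fit in the image height")
  TRUE
})

#' Synthetic phantom with ground truth
#'
#' A generated phantom scan plus every planted truth: band boundaries, the
#' true Haller boundary (constructed with the same two-stage interpolation
#' the pipeline applies to true anchor points), the lumen mask, and the
#' per-vessel geometry table.
#'
#' @slot scan the speckled phantom as a [BScan-class].
#' @slot cleanPixels the noise-free render (matrix in \[0, 1\]).
#' @slot speckleField the multiplicative noise field applied.
#' @slot cib,cob,hallerTruth ground-truth [BoundaryCurve-class] objects.
#' @slot lumenMask logical matrix of planted vessel lumens.
#' @slot vesselTruth data.frame: \code{center_row}, \code{center_col},
#'   \code{radius_row}, \code{radius_col}, \code{stratum}.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomTruth",
  representation(
    scan = "BScan", cleanPixels = "matrix", speckleField = "matrix",
    cib = "BoundaryCurve", cob = "BoundaryCurve",
    hallerTruth = "BoundaryCurve", lumenMask = "matrix",
    vesselTruth = "data.frame", spec = "PhantomSpec"
  )
)

#' End-to-end segmentation result
#'
#' Everything the demarcation pipeline produced for one scan, kept so
#' intermediate stages can be inspected or dumped.
#'
#' @slot haller the [HallerBoundary-class] result.
#' @slot large the [LargeVesselSet-class] classification.
#' @slot vessels the [VesselLabelMap-class].
#' @slot bcl the closed [BinarizedChoroid-class] the watershed ran on.
#' @slot binary the pre-restriction Otsu mask (lumen = TRUE).
#' @slot preprocessed the [PreprocessedBScan-class].
#' @slot config the [PipelineConfig-class] used.
#' @export
setClass("HallerSegmentation",
  representation(
    haller = "HallerBoundary", large = "LargeVesselSet",
    vessels = "VesselLabelMap", bcl = "BinarizedChoroid",
    binary = "matrix", preprocessed = "PreprocessedBScan",
    config = "PipelineConfig"
  )
)
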